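# Season-by-species capture-event counts from a published two-year
# camera-trap survey of eight sympatric mammals in a boreal forest in
# Hokkaido, Japan (30 cameras, 20,344 trap-days in total).
species,winter,spring,summer,autumn
squirrel,7,57,110,95
raccoon_dog,18,185,400,129
raccoon,0,26,31,22
deer,59,4200,4236,2670
hare,64,71,51,66
bear,0,28,19,16
fox,35,222,173,155
marten,11,34,51,38
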