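archetype,x,y,weight
ST_arcuate,21,3,0.7
ST_arcuate,15,9,1
ST_arcuate,9,9,1
ST_arcuate,3,9,0.9
ST_arcuate,9,15,1
ST_arcuate,3,15,1
ST_arcuate,-3,15,1
ST_arcuate,-9,15,0.9
ST_arcuate,-9,9,0.8
ST_arcuate,-15,9,0.7
IN_arcuate,-3,-9,0.8
IN_arcuate,-9,-9,1
IN_arcuate,-15,-9,1
IN_arcuate,-21,-9,1
IN_arcuate,-9,-15,1
IN_arcuate,-15,-15,0.9
IN_arcuate,-21,-3,0.8
IN_arcuate,-27,-3,0.8
nasal_step,-27,3,1
nasal_step,-21,3,1
nasal_step,-15,3,1
nasal_step,-9,3,0.8
nasal_step,-21,9,0.6
paracentral,-3,3,1
paracentral,3,3,1
paracentral,3,9,0.9
paracentral,-3,9,0.9
diffuse_accent,15,9,1.5
diffuse_accent,9,9,1.5
diffuse_accent,9,15,1.5
diffuse_accent,3,9,1.4
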