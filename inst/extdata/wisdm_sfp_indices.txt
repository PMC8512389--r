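0,2,3,5,6,7,9,12,14,15,20,21,22,23,25,33,35,36,37,39,40,42,43,44,45,46,47,49,50,53,55,56,59,60,61,63,65,66,68,69,70,71,73,78,80,81,88,89,90,91,92,104,105,109,118,119,122,125,127,128,129,133,135,136,138,139,141,145,148,150,152,155,156,159,161,164,169,171,175,178,179,180,181
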