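0,5,9,10,11,15,16,20,21,27,31,36,45,50,51,54,58,59,61,64,70,76,80,81,82,85,86,90,91,96,98,99,105,108,110,111,116,123,125,126,128,130,131,137,141,145,146,148,150,151,156,158,160,161,164,166,167,168,172,178,181
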