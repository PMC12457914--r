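table,category,blank,filled
T2,0,0,46
T2,1,9,35
T3,0,1,44
T3,1,8,37
T4,0,1,44
T4,1,9,36
T5,0,19,26
T5,1,2,43
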