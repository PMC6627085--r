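well,row,v1,v2,v3,v4,v5
A1,1,1,2,3,4,5
A1,2,6,7,8,9,10
A1,3,11,12,13,14,15
A1,4,16,17,18,19,20
A1,5,21,22,23,24,25
A2,1,210,210,210,210,210
A2,2,210,210,210,210,210
A2,3,210,210,210,210,210
A2,4,210,210,210,210,210
A2,5,210,210,210,210,210
A3,1,100,100,100,100,100
A3,2,100,100,100,100,100
A3,3,100,100,100,100,100
A3,4,100,100,100,100,100
A3,5,100,100,100,100,100
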