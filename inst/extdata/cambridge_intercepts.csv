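freq_khz,intercept_db
0.125,-14
0.25,-9
0.5,-8
0.75,-6
1,0
1.5,1
2,1
3,3
4,1
6,-1
8,-2
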