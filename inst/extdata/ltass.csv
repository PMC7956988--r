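freq_hz,rel_db
80,-6
100,-2
125,2
160,6
200,8
250,8
315,8
400,8
500,7
630,5
800,2
1000,0
1250,-2
1600,-4
2000,-6
2500,-8
3150,-10
4000,-12
5000,-14
6300,-16
8020,-18
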