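freq_hz,ref_db_spl
80,33
125,22.1
250,11.4
500,4.4
750,3
1000,2.4
1500,0.5
2000,-1.3
3000,-5.8
4000,-5.4
6000,4.3
8020,12.6
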