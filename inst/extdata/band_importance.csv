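freq_hz,spin,nns,flat
80,0.2,0.4,1
125,0.4,0.6,1
250,1.0,1.4,1
500,2.4,2.6,1
800,3.4,3.2,1
1250,4.2,3.8,1
2000,4.6,4.2,1
3150,4.0,3.8,1
4000,3.2,3.2,1
5000,2.4,2.6,1
6300,1.6,1.8,1
8020,1.0,1.2,1
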