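mass_g,phi
0.1,0.88
1,0.95
3,0.97
10,0.98
30,0.99
100,0.992
300,0.995
1000,0.997
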