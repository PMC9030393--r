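weld_time_s,max,min,mean
10,0.13,0.05,0.097
15,0.20,0.10,0.154
20,0.28,0.20,0.244
25,0.36,0.29,0.321
30,0.88,0.55,0.697
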