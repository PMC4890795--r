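"time_min","value"
-30,0.394
30,0.749
60,3.376
90,2.233
120,1.1354
150,1.2174
180,1.1149
210,0.5639
240,0.3713
300,1.2651
360,0.5854
420,0.223
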