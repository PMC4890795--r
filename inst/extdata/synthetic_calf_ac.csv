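"time_min","value"
-30,0
30,4.9861
60,6.4786
90,10.1759
120,15.0331
150,14.4366
180,15.1285
210,13.6764
240,14.1534
300,14.8795
360,13.1545
420,11.8077
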