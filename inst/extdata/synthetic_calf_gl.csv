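"time_min","value"
-30,5.527
30,7.0133
60,7.6083
90,6.5694
120,6.4074
150,7.2044
180,6.1936
210,5.4896
240,5.7067
300,7.0656
360,5.4648
420,5.6038
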