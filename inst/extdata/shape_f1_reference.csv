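dataset,f1_other,f1_atypical,f1_round,macro_f1
day,0.640,0.272,0.382,0.431
week,0.734,0.672,0.654,0.687
month,0.787,0.520,0.575,0.627
full,0.826,0.752,0.852,0.81
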