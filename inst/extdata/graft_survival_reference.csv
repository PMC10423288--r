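experiment,label,n_grafted,percent_alive,n_remaining
a,Excellent,15,60,9
a,Medium,22,63,14
a,Poor,10,20,2
b,Medium,20,70,14
b,Poor,20,0,0
c,Medium,50,76,38
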