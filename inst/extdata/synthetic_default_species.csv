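name,family,param1,param2,feed_amount
free_protein,point,6,0,100
exomere,truncnorm,45.6,10.7,1
small_ev,truncnorm,60,15,2
large_ev,truncnorm,100,25,2
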