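marker_id	mean_beta
cgs00107	0.44867048393934966
cgs00153	0.4064178190426901
cgs00154	0.5062417582608759
cgs00155	0.4414777205325663
cgs00156	0.4926661120261997
cgs00157	0.3545170904602855
cgs00158	0.4434582591289654
cgs00159	0.4697516059037298
cgs00160	0.5319747336674482
cgs00161	0.55830585565418
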