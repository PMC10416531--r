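marker_id	weight
(Intercept)	-2.6101885724372957
cgs00107	-0.5
cgs00153	0.6111111111111112
cgs00154	-0.7222222222222222
cgs00155	-0.8333333333333333
cgs00156	-0.9444444444444444
cgs00157	-1.0555555555555556
cgs00158	-1.1666666666666665
cgs00159	1.2777777777777777
cgs00160	1.3888888888888888
cgs00161	1.5
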