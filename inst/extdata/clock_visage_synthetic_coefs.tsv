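marker_id	weight
(Intercept)	-60.00597490118817
cgs00001	28
cgs00002	30
cgs00003	32
cgs00004	34
cgs00005	36
cgs00006	38
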