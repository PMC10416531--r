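marker_id	mean_beta
cgs00001	0.4371657070238143
cgs00002	0.5221174519509078
cgs00003	0.6012849416118116
cgs00004	0.4913178470684215
cgs00005	0.6273390002083034
cgs00006	0.46241270017344505
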