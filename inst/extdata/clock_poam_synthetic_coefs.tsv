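marker_id	weight
(Intercept)	1.238762505273309
cgs00107	-0.05
cgs00108	0.052222222222222225
cgs00109	-0.05444444444444445
cgs00110	0.05666666666666667
cgs00111	-0.05888888888888889
cgs00112	-0.061111111111111116
cgs00113	-0.06333333333333334
cgs00114	0.06555555555555556
cgs00115	-0.06777777777777778
cgs00116	0.07
cgs00117	0.07222222222222223
cgs00118	0.07444444444444445
cgs00119	0.07666666666666666
cgs00120	-0.0788888888888889
cgs00121	-0.0811111111111111
cgs00122	-0.08333333333333334
cgs00123	0.08555555555555555
cgs00124	0.08777777777777779
cgs00125	0.09
cgs00126	0.09222222222222223
cgs00127	0.09444444444444444
cgs00128	-0.09666666666666668
cgs00129	-0.09888888888888889
cgs00130	-0.10111111111111112
cgs00131	0.10333333333333333
cgs00132	-0.10555555555555556
cgs00133	0.10777777777777778
cgs00134	-0.11
cgs00135	-0.11222222222222222
cgs00136	-0.11444444444444445
cgs00137	0.11666666666666667
cgs00138	-0.11888888888888889
cgs00139	0.12111111111111111
cgs00140	0.12333333333333334
cgs00141	-0.12555555555555556
cgs00142	-0.12777777777777777
cgs00143	0.13
cgs00144	-0.13222222222222224
cgs00145	0.13444444444444445
cgs00146	-0.13666666666666666
cgs00147	0.1388888888888889
cgs00148	0.14111111111111113
cgs00149	-0.14333333333333334
cgs00150	-0.14555555555555555
cgs00151	-0.14777777777777779
cgs00152	-0.15
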