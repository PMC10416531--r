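marker_id	mean_beta
cgs00107	0.3901008166838437
cgs00108	0.48209962211549284
cgs00109	0.39725456177257
cgs00110	0.6140364724909887
cgs00111	0.5573423930443824
cgs00112	0.49460872663185
cgs00113	0.39087032987736164
cgs00114	0.3882056715199724
cgs00115	0.6323411504272372
cgs00116	0.4555706990882754
cgs00117	0.35177369781304146
cgs00118	0.6215885402867571
cgs00119	0.5833771650912241
cgs00120	0.58871482857503
cgs00121	0.5385032768594101
cgs00122	0.38237919325474645
cgs00123	0.4136539245722815
cgs00124	0.3815361704910174
cgs00125	0.41186846073251215
cgs00126	0.3925556063652038
cgs00127	0.6250469418242575
cgs00128	0.5817360375542193
cgs00129	0.4275015090126544
cgs00130	0.3604656470241025
cgs00131	0.503128740657121
cgs00132	0.3525033654645085
cgs00133	0.5520860169781372
cgs00134	0.47547136759385467
cgs00135	0.5287290466716513
cgs00136	0.45350527577102184
cgs00137	0.5977573879761622
cgs00138	0.36881302981637415
cgs00139	0.4625355396186933
cgs00140	0.6303554418031126
cgs00141	0.6397632874082775
cgs00142	0.5516900976421312
cgs00143	0.41201364221051334
cgs00144	0.5347979698795825
cgs00145	0.5288989832624793
cgs00146	0.41878447025083004
cgs00147	0.3585960551397875
cgs00148	0.5005958252120764
cgs00149	0.46075435508973894
cgs00150	0.39457044950686393
cgs00151	0.596179892285727
cgs00152	0.46730220892932267
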