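name	degree	a	b	c
hannum_hts	1	0.64	0.89	NA
hannum_epic	1	-5.16	1.1	NA
visage_ampliseq	1	-1.61	0.93	NA
poam_hts	1	0.23	0.72	NA
mrs_cont_hts	1	-1.72	0.61	NA
mrs_cat_hts	2	25.76	13.29	1.81
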