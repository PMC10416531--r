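marker_id	mean_beta
cgs00001	0.5147495836019516
cgs00002	0.48824261312838646
cgs00003	0.40185914966277775
cgs00004	0.6279807722894475
cgs00005	0.41850734483450647
cgs00006	0.6246230299351737
cgs00007	0.5036786213051527
cgs00008	0.6125301552936435
cgs00009	0.39908310873433944
cgs00010	0.6218709690729156
cgs00011	0.5736766680609435
cgs00012	0.3750115340342745
cgs00013	0.3814121547155082
cgs00014	0.5278497169259936
cgs00015	0.5848484096117318
cgs00016	0.4365691757760942
cgs00017	0.39106525941751896
cgs00018	0.47446742493193594
cgs00019	0.6300352463964374
cgs00020	0.6469815137796104
cgs00021	0.5359184744302183
cgs00022	0.6355471345130355
cgs00023	0.5989064685301855
cgs00024	0.49874942828901114
cgs00025	0.4498346886597574
cgs00026	0.6496485180221498
cgs00027	0.6203173050191253
cgs00028	0.47077123934868725
cgs00029	0.48180698172654957
cgs00030	0.6193780464818701
cgs00031	0.3936002173926681
cgs00032	0.5443846456240863
cgs00033	0.4535846849437803
cgs00034	0.6148776089074091
cgs00035	0.6047774269711226
cgs00036	0.6383162801386788
cgs00037	0.3547979935305193
cgs00038	0.6360836006933823
cgs00039	0.5942830298095941
cgs00040	0.414292228850536
cgs00041	0.5960810174699873
cgs00042	0.48623734721913936
cgs00043	0.4312722642673179
cgs00044	0.4571652882033959
cgs00045	0.41620860900729895
cgs00046	0.49072271490003916
cgs00047	0.49218562375754116
cgs00048	0.4461151066003367
cgs00049	0.5436062218388542
cgs00050	0.4174759160261601
cgs00051	0.4737497241236269
cgs00052	0.43977847616188226
cgs00053	0.4650011884048581
cgs00054	0.4046478988835588
cgs00055	0.38268332250881937
cgs00056	0.5123354379786178
cgs00057	0.6171837243018672
cgs00058	0.485294581274502
cgs00059	0.640058532403782
cgs00060	0.38150304947048425
cgs00061	0.5473222591914236
cgs00062	0.637077038246207
cgs00063	0.5912768074311316
cgs00064	0.5398796622641384
cgs00065	0.6356325905304403
cgs00066	0.379605962568894
cgs00067	0.3938325906405225
cgs00068	0.6340264950878918
cgs00069	0.5070228898897767
cgs00070	0.436631007748656
cgs00071	0.6403125352226198
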