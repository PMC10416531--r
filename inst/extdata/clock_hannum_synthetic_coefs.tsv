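marker_id	weight
(Intercept)	51.21906748455151
cgs00001	-1.5
cgs00002	-1.5214285714285714
cgs00003	-1.542857142857143
cgs00004	1.5642857142857143
cgs00005	1.5857142857142856
cgs00006	-1.6071428571428572
cgs00007	-1.6285714285714286
cgs00008	-1.65
cgs00009	-1.6714285714285715
cgs00010	1.6928571428571428
cgs00011	-1.7142857142857144
cgs00012	1.7357142857142858
cgs00013	-1.7571428571428571
cgs00014	1.7785714285714285
cgs00015	-1.8
cgs00016	-1.8214285714285714
cgs00017	1.842857142857143
cgs00018	1.8642857142857143
cgs00019	-1.8857142857142857
cgs00020	1.907142857142857
cgs00021	-1.9285714285714286
cgs00022	1.95
cgs00023	-1.9714285714285715
cgs00024	1.9928571428571429
cgs00025	2.0142857142857142
cgs00026	-2.0357142857142856
cgs00027	2.057142857142857
cgs00028	-2.0785714285714287
cgs00029	-2.1
cgs00030	-2.1214285714285714
cgs00031	2.142857142857143
cgs00032	2.164285714285714
cgs00033	2.185714285714286
cgs00034	2.2071428571428573
cgs00035	2.2285714285714286
cgs00036	2.25
cgs00037	2.2714285714285714
cgs00038	-2.2928571428571427
cgs00039	2.314285714285714
cgs00040	-2.335714285714286
cgs00041	-2.357142857142857
cgs00042	2.3785714285714286
cgs00043	-2.4
cgs00044	2.4214285714285717
cgs00045	-2.442857142857143
cgs00046	-2.4642857142857144
cgs00047	-2.4857142857142858
cgs00048	-2.507142857142857
cgs00049	-2.5285714285714285
cgs00050	-2.55
cgs00051	2.571428571428571
cgs00052	-2.592857142857143
cgs00053	2.6142857142857143
cgs00054	-2.6357142857142857
cgs00055	2.6571428571428575
cgs00056	-2.678571428571429
cgs00057	-2.7
cgs00058	-2.7214285714285715
cgs00059	-2.742857142857143
cgs00060	-2.7642857142857142
cgs00061	-2.7857142857142856
cgs00062	-2.807142857142857
cgs00063	2.8285714285714283
cgs00064	2.85
cgs00065	-2.8714285714285714
cgs00066	2.892857142857143
cgs00067	-2.9142857142857146
cgs00068	2.935714285714286
cgs00069	2.9571428571428573
cgs00070	2.9785714285714286
cgs00071	3
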