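"week","sex","p03","p10","p50","p90"
22,"male",221,242,286,330
23,"male",319,348,411,475
24,"male",435,475,562,648
25,"male",568,621,734,847
26,"male",714,780,922,1064
27,"male",868,949,1121,1294
28,"male",1027,1122,1326,1530
29,"male",1185,1296,1531,1766
30,"male",1341,1465,1731,1998
31,"male",1489,1628,1924,2219
32,"male",1630,1781,2105,2429
33,"male",1761,1924,2274,2624
34,"male",1881,2056,2430,2803
35,"male",1991,2176,2571,2967
36,"male",2090,2284,2699,3114
37,"male",2179,2381,2814,3246
38,"male",2258,2467,2916,3364
39,"male",2327,2544,3006,3468
40,"male",2389,2611,3085,3560
41,"male",2443,2670,3155,3640
42,"male",2490,2721,3216,3711
22,"female",208,228,269,311
23,"female",300,328,387,447
24,"female",410,448,529,610
25,"female",535,585,691,797
26,"female",672,735,868,1002
27,"female",818,894,1056,1219
28,"female",967,1057,1249,1441
29,"female",1116,1220,1442,1664
30,"female",1262,1380,1630,1881
31,"female",1403,1533,1812,2090
32,"female",1535,1678,1983,2287
33,"female",1658,1812,2142,2471
34,"female",1772,1936,2288,2640
35,"female",1875,2049,2422,2794
36,"female",1968,2151,2542,2933
37,"female",2052,2242,2650,3057
38,"female",2126,2323,2746,3168
39,"female",2192,2395,2831,3266
40,"female",2250,2459,2906,3352
41,"female",2301,2514,2971,3428
42,"female",2345,2563,3029,3494
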