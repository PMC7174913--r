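age,qx
0,0.00063180033
1,0.00063516367
2,0.00063888072
3,0.00064298868
4,0.00064752865
5,0.00065254608
6,0.00065809116
7,0.0006642194
8,0.00067099209
9,0.00067847703
10,0.0006867491
11,0.00069589107
12,0.00070599441
13,0.00071716021
14,0.00072950018
15,0.00074313779
16,0.00075820945
17,0.00077486595
18,0.00079327391
19,0.00081361746
20,0.00083610007
21,0.00086094661
22,0.00088840557
23,0.00091875153
24,0.00095228793
25,0.00098935008
26,0.0010303085
27,0.0010755726
28,0.0011255947
29,0.0011808749
30,0.0012419653
31,0.0013094763
32,0.0013840822
33,0.001466528
34,0.0015576368
35,0.0016583179
36,0.001769576
37,0.0018925207
38,0.002028378
39,0.002178502
40,0.0023443884
41,0.0025276892
42,0.0027302287
43,0.0029540217
44,0.0032012927
45,0.0034744981
46,0.0037763497
47,0.0041098409
48,0.0044782758
49,0.0048853009
50,0.0053349395
51,0.0058316307
52,0.0063802708
53,0.0069862597
54,0.0076555512
55,0.0083947078
56,0.0092109618
57,0.01011228
58,0.011107438
59,0.012206093
60,0.013418875
61,0.014757474
62,0.016234742
63,0.017864799
64,0.019663149
65,0.021646803
66,0.023834411
67,0.026246402
68,0.028905131
69,0.031835038
70,0.035062803
71,0.038617519
72,0.042530856
73,0.046837235
74,0.051573992
75,0.056781539
76,0.062503513
77,0.068786901
78,0.075682141
79,0.083243182
80,0.091527495
81,0.10059602
82,0.11051302
83,0.12134585
84,0.13316457
85,0.14604143
86,0.16005016
87,0.17526503
88,0.19175966
89,0.20960555
90,0.22887029
91,0.24961537
92,0.27189363
93,0.2957463
94,0.32119962
95,0.3482611
96,0.37691542
97,0.4071201
98,0.43880107
99,0.47184837
100,1
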