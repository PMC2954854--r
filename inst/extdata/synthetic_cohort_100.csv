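id,risk,outcome
1,0.09776756845,0
2,0.3284491211,0
3,0.1760284562,0
4,0.3518660979,0
5,0.07698114111,0
6,0.6856921915,1
7,0.028560607,0
8,0.02423835846,0
9,0.01166356759,0
10,0.4519505813,0
11,0.469101141,1
12,0.6020111167,1
13,0.5860987429,1
14,0.02569414311,0
15,0.1830694404,0
16,0.7861250219,1
17,0.5910456298,1
18,0.1900704622,0
19,0.1189679149,0
20,0.02467031357,0
21,0.1276187302,0
22,0.005827737579,0
23,0.0124542242,0
24,0.06291334358,0
25,0.006097460553,0
26,0.2060671035,0
27,0.04652055291,0
28,0.6524002044,1
29,0.2323477274,0
30,0.06315720509,0
31,0.3833939557,0
32,0.3259903757,0
33,0.04257037023,0
34,0.1206076603,0
35,0.1969474242,0
36,0.03648515554,0
37,0.04487312551,0
38,0.1020034971,0
39,0.2343947876,0
40,0.3145774142,0
41,0.2989190784,0
42,0.06319184482,0
43,0.3509799041,1
44,0.03226819802,0
45,0.4811440917,0
46,0.380914518,0
47,0.1416353391,0
48, 0.10476829,0
49,0.07602113772,0
50,0.05149589182,0
51,0.1228014301,0
52,0.3397994758,0
53,0.2638489862,0
54,0.1645432765,0
55,0.6716707592,1
56,0.2647910681,0
57,0.304493329,0
58,0.2780964789,0
59,0.3199519191,0
60,0.1592562567,0
61,0.2269021766,0
62,0.2099076197,0
63,0.1347087767,0
64,0.1679742403,0
65,0.1905260574,0
66,0.1303300922,0
67,0.1553838379,0
68,0.3560241874,0
69,0.2594223081,0
70,0.4139760588,0
71,0.2532644356,0
72,0.4406812081,1
73,0.224650827,0
74,0.05299623803,0
75,0.2179122727,0
76,0.02406709663,0
77,0.1394100271,0
78,0.4505037516,0
79,0.2573726271,0
80,0.2951715099,0
81,0.326162117,0
82,0.008812145811,0
83,0.4710304375,0
84,0.2562193571,1
85,0.1327773314,0
86,0.6692673191,1
87,0.3846623143,0
88,0.1405818243,0
89,0.2051290324,0
90,0.309150514,0
91, 0.15984038,0
92,0.04928874793,0
93,0.1545543881,0
94,0.6983460138,1
95, 0.25457607,0
96,0.2530690514,0
97,0.06304465705,0
98,0.03151111616,0
99,0.05376102429,0
100,0.2353413733,0
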