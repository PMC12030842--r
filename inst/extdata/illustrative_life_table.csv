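"age","survival"
0,1
1,0.99936881
2,0.99873506
3,0.99809849
4,0.99745879
5,0.99681564
6,0.99616869
7,0.99551754
8,0.99486177
9,0.99420091
10,0.99353446
11,0.99286185
12,0.99218249
13,0.9914957
14,0.99080077
15,0.99009689
16,0.9893832
17,0.98865874
18,0.9879225
19,0.98717332
20,0.98640997
21,0.98563111
22,0.98483525
23,0.98402077
24,0.98318592
25,0.98232876
26,0.98144718
27,0.9805389
28,0.97960139
29,0.97863192
30,0.97762748
31,0.97658482
32,0.97550035
33,0.97437019
34,0.97319009
35,0.97195541
36,0.97066109
37,0.96930162
38,0.96787099
39,0.96636266
40,0.96476949
41,0.96308371
42,0.96129686
43,0.95939974
44,0.95738235
45,0.9552338
46,0.95294228
47,0.95049497
48,0.94787794
49,0.9450761
50,0.94207313
51,0.93885133
52,0.93539159
53,0.93167328
54,0.92767415
55,0.92337025
56,0.91873581
57,0.9137432
58,0.90836282
59,0.90256304
60,0.89631012
61,0.88956823
62,0.88229936
63,0.87446339
64,0.86601812
65,0.85691936
66,0.84712108
67,0.83657564
68,0.82523405
69,0.81304641
70,0.79996233
71,0.78593159
72,0.77090486
73,0.75483461
74,0.73767619
75,0.71938908
76,0.69993833
77,0.67929622
78,0.6574441
79,0.63437447
80,0.61009317
81,0.58462174
82,0.55799985
83,0.53028771
84,0.50156846
85,0.47195017
86,0.44156761
87,0.4105833
88,0.3791878
89,0.34759902
90,0.31606016
91,0.28483627
92,0.2542091
93,0.22447027
94,0.19591273
95,0.16882069
96,0.14345843
97,0.12005851
98,0.098810157
99,0.079848805
100,0.063247818
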