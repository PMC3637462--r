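"age","count"
30,75860
31,73913
32,72016
33,70168
34,68367
35,66613
36,64903
37,63237
38,61614
39,60033
40,58492
41,56991
42,55528
43,54103
44,52715
45,51362
46,50044
47,48759
48,47508
49,46288
50,45100
51,43943
52,42815
53,41716
54,40646
55,44357
56,43219
57,42110
58,41029
59,39976
60,38950
61,37950
62,36976
63,36027
64,35103
65,34202
66,33324
67,32469
68,31635
69,30823
70,30032
71,29262
72,28511
73,27779
74,27066
75,23545
76,22940
77,22352
78,21778
79,21219
80,20674
81,20144
82,19627
83,19123
84,18632
85,18154
86,17688
87,17234
88,16792
89,16361
90,15941
91,15532
92,15133
93,14745
94,14366
95,13998
96,13638
97,13288
98,12947
99,12615
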