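age	sex	count
0	female	158123
1	female	157645
2	female	157467
3	female	157398
4	female	157369
5	female	157355
6	female	157345
7	female	157337
8	female	157329
9	female	157321
10	female	157311
11	female	157301
12	female	157290
13	female	157278
14	female	157264
15	female	157249
16	female	157233
17	female	157215
18	female	157195
19	female	157173
20	female	157150
21	female	157123
22	female	157094
23	female	157063
24	female	157028
25	female	156989
26	female	156947
27	female	156901
28	female	156850
29	female	156794
30	female	156732
31	female	156664
32	female	156590
33	female	156508
34	female	156418
35	female	156319
36	female	156211
37	female	156092
38	female	155960
39	female	155816
40	female	155658
41	female	155484
42	female	155293
43	female	155084
44	female	154853
45	female	154600
46	female	154323
47	female	154018
48	female	153684
49	female	153317
50	female	152915
51	female	152473
52	female	151990
53	female	151460
54	female	150879
55	female	150243
56	female	149546
57	female	148784
58	female	147950
59	female	147039
60	female	146043
61	female	144956
62	female	143770
63	female	142477
64	female	141068
65	female	139535
66	female	137869
67	female	136059
68	female	134097
69	female	131972
70	female	129673
71	female	127192
72	female	124518
73	female	121643
74	female	118558
75	female	115255
76	female	111730
77	female	107977
78	female	103996
79	female	99788
80	female	95356
81	female	90709
82	female	85861
83	female	80828
84	female	75633
85	female	70305
86	female	64878
87	female	59393
88	female	53895
89	female	48435
90	female	43067
91	female	37849
92	female	32837
93	female	28088
94	female	23655
95	female	19584
96	female	15911
97	female	12662
98	female	9850
99	female	7473
100	female	5515
0	male	158123
1	male	157645
2	male	157467
3	male	157398
4	male	157369
5	male	157355
6	male	157345
7	male	157337
8	male	157329
9	male	157321
10	male	157311
11	male	157301
12	male	157290
13	male	157278
14	male	157264
15	male	157249
16	male	157233
17	male	157215
18	male	157195
19	male	157173
20	male	157150
21	male	157123
22	male	157094
23	male	157063
24	male	157028
25	male	156989
26	male	156947
27	male	156901
28	male	156850
29	male	156794
30	male	156732
31	male	156664
32	male	156590
33	male	156508
34	male	156418
35	male	156319
36	male	156211
37	male	156092
38	male	155960
39	male	155816
40	male	155658
41	male	155484
42	male	155293
43	male	155084
44	male	154853
45	male	154600
46	male	154323
47	male	154018
48	male	153684
49	male	153317
50	male	152915
51	male	152473
52	male	151990
53	male	151460
54	male	150879
55	male	150243
56	male	149546
57	male	148784
58	male	147950
59	male	147039
60	male	146043
61	male	144956
62	male	143770
63	male	142477
64	male	141068
65	male	139535
66	male	137869
67	male	136059
68	male	134097
69	male	131972
70	male	129673
71	male	127192
72	male	124518
73	male	121643
74	male	118558
75	male	115255
76	male	111730
77	male	107977
78	male	103996
79	male	99788
80	male	95356
81	male	90709
82	male	85861
83	male	80828
84	male	75633
85	male	70305
86	male	64878
87	male	59393
88	male	53895
89	male	48435
90	male	43067
91	male	37849
92	male	32837
93	male	28088
94	male	23655
95	male	19584
96	male	15911
97	male	12662
98	male	9850
99	male	7473
100	male	5515
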