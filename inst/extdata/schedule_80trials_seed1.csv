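# seed: 1
"trial_index","sentence_index"
1,7
2,4
3,1
4,4
5,5
6,2
7,6
8,6
9,3
10,6
11,1
12,4
13,7
14,8
15,5
16,4
17,2
18,4
19,1
20,1
21,5
22,4
23,5
24,7
25,3
26,6
27,7
28,3
29,7
30,4
31,8
32,3
33,6
34,8
35,6
36,5
37,3
38,4
39,8
40,1
41,2
42,3
43,5
44,8
45,5
46,6
47,4
48,2
49,2
50,1
51,2
52,1
53,5
54,2
55,6
56,7
57,8
58,6
59,7
60,3
61,2
62,3
63,8
64,8
65,1
66,2
67,7
68,8
69,1
70,6
71,7
72,1
73,5
74,5
75,7
76,3
77,4
78,3
79,2
80,8
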