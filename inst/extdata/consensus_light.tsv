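pos	aa
1	D
2	I
3	Q
4	M
5	T
6	Q
7	S
8	P
9	S
10	S
11	L
12	S
13	A
14	S
15	V
16	G
17	D
18	R
19	V
20	T
21	I
22	T
23	C
24	R
25	A
26	S
27	Q
28	S
29	I
30	S
31	S
32	Y
33	L
34	N
35	W
36	Y
37	Q
38	Q
39	K
40	P
41	G
42	K
43	A
44	P
45	K
46	L
47	L
48	I
49	Y
50	A
51	A
52	S
53	S
54	L
55	Q
56	S
57	G
58	V
59	P
60	S
61	R
62	F
63	S
64	G
65	S
66	G
67	S
68	G
69	T
70	D
71	F
72	T
73	L
74	T
75	I
76	S
77	S
78	L
79	Q
80	P
81	E
82	D
83	F
84	A
85	T
86	Y
87	Y
88	C
89	Q
90	Q
91	S
92	Y
93	S
94	T
95	P
96	P
97	T
98	F
99	G
100	Q
101	G
102	T
103	K
104	V
105	E
106	I
107	K
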