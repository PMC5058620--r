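pos	aa
1	E
2	V
3	Q
4	L
5	L
6	E
7	S
8	G
9	G
10	G
11	L
12	V
13	Q
14	P
15	G
16	G
17	S
18	L
19	R
20	L
21	S
22	C
23	A
24	A
25	S
26	G
27	F
28	T
29	F
30	S
31	S
32	Y
33	A
34	M
35	S
36	W
37	V
38	R
39	Q
40	A
41	P
42	G
43	K
44	G
45	L
46	E
47	W
48	V
49	S
50	A
51	I
52	S
53	G
54	S
55	G
56	G
57	S
58	T
59	Y
60	Y
61	A
62	D
63	S
64	V
65	K
66	G
67	R
68	F
69	T
70	I
71	S
72	R
73	D
74	N
75	S
76	K
77	N
78	T
79	L
80	Y
81	L
82	Q
83	M
84	N
85	S
86	L
87	R
88	A
89	E
90	D
91	T
92	A
93	V
94	Y
95	Y
96	C
97	A
98	K
99	D
100	R
101	G
102	Y
103	S
104	S
105	G
106	W
107	Y
108	F
109	D
110	Y
111	W
112	G
113	Q
114	G
115	T
116	L
117	V
118	T
119	V
120	S
121	S
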