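order,reference,index
1,0,0
2,0,0
3,1,1
4,0,0
5,0,1
6,1,0
7,0,0
8,0,0
9,1,1
10,0,0
11,0,1
12,1,1
13,0,0
14,0,0
15,0,0
16,1,1
17,0,0
18,0,1
19,1,0
20,0,0
21,0,0
22,1,1
23,0,0
24,0,1
25,1,1
26,0,0
27,0,0
28,1,0
29,0,0
30,0,0
31,1,1
32,0,0
33,0,0
34,1,0
35,0,1
36,0,0
37,1,1
38,0,0
39,0,0
40,1,1
41,0,0
42,0,0
43,1,0
44,0,0
45,0,1
46,1,1
47,0,0
48,1,0
49,1,1
50,0,0
51,1,0
52,0,0
53,1,1
54,1,0
55,0,0
56,1,1
57,0,0
58,1,0
59,0,0
60,1,1
61,1,0
62,0,0
63,1,1
64,0,0
65,0,0
66,1,1
67,0,0
68,0,1
69,1,0
70,0,0
71,0,0
72,1,1
73,0,0
74,0,1
75,1,1
76,0,0
77,0,0
78,1,0
79,0,0
80,1,1
81,0,0
82,0,1
83,1,0
84,0,0
85,1,1
86,0,0
87,0,0
88,1,0
89,0,0
90,1,1
91,0,0
92,0,1
93,1,0
94,0,0
95,1,1
96,0,0
97,0,0
98,1,0
99,0,0
100,1,1
101,0,1
102,0,0
103,1,0
104,0,0
105,1,0
106,0,0
107,0,0
108,1,1
109,0,1
110,1,0
111,0,0
112,0,0
113,1,1
114,0,0
115,1,0
116,0,0
117,0,0
118,1,1
119,0,1
120,1,0
121,0,0
122,0,0
123,1,1
124,0,0
125,1,0
126,0,0
127,0,1
128,1,1
129,0,0
130,0,0
131,1,1
132,0,0
133,0,0
134,1,0
135,0,0
136,1,1
137,0,0
138,0,0
139,1,1
140,0,0
141,0,0
142,1,1
143,0,0
144,1,0
145,0,0
146,0,0
147,1,1
148,0,0
149,0,1
150,1,1
151,0,0
152,0,0
153,1,0
154,0,0
155,0,0
156,1,1
157,0,0
158,1,1
159,0,1
160,0,0
161,1,0
162,0,0
163,0,0
164,1,1
165,0,0
166,0,0
167,1,0
168,0,0
169,1,1
170,0,1
171,0,0
172,1,1
173,0,0
174,0,0
175,1,0
176,0,0
177,0,0
178,1,1
179,0,1
180,0,0
181,1,1
182,0,0
183,1,0
184,0,0
185,0,0
186,1,1
187,0,0
188,0,0
189,1,0
190,0,1
191,0,0
192,1,1
193,0,0
194,1,1
195,0,0
196,0,0
197,1,0
198,0,0
199,0,1
200,1,1
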