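order,reference,index
1,0,0
2,1,1
3,1,0
4,0,0
5,1,1
6,1,1
7,0,0
8,1,1
9,1,0
10,0,0
11,1,1
12,1,1
13,0,0
14,1,0
15,1,1
16,0,0
17,1,1
18,1,1
19,0,0
20,1,0
21,1,1
22,0,1
23,1,1
24,0,0
25,1,1
26,0,0
27,1,0
28,0,0
29,1,1
30,1,1
31,0,0
32,1,1
33,0,0
34,1,0
35,0,0
36,1,1
37,1,0
38,0,0
39,1,1
40,0,1
41,1,1
42,0,0
43,1,1
44,0,0
45,1,0
46,1,1
47,0,0
48,1,1
49,0,0
50,1,1
51,0,1
52,1,0
53,0,0
54,1,1
55,1,1
56,0,0
57,1,0
58,0,0
59,1,1
60,0,0
61,1,1
62,1,1
63,0,1
64,1,0
65,0,0
66,1,1
67,0,0
68,1,1
69,0,0
70,1,1
71,1,0
72,0,0
73,1,1
74,0,1
75,1,1
76,0,0
77,0,0
78,1,0
79,0,0
80,0,1
81,1,1
82,0,0
83,0,0
84,0,0
85,1,0
86,0,0
87,0,1
88,1,1
89,0,0
90,0,0
91,1,0
92,0,0
93,0,1
94,1,1
95,0,0
96,0,0
97,1,0
98,0,0
99,1,1
100,0,0
101,0,0
102,1,1
103,0,1
104,1,0
105,0,0
106,0,0
107,1,1
108,0,0
109,1,0
110,0,0
111,0,1
112,1,1
113,0,0
114,1,1
115,0,0
116,0,0
117,1,0
118,0,0
119,1,1
120,0,0
121,0,1
122,1,0
123,0,0
124,0,0
125,1,1
126,0,0
127,1,0
128,0,0
129,0,0
130,1,1
131,0,1
132,1,1
133,0,0
134,0,0
135,1,0
136,0,0
137,1,1
138,0,0
139,0,1
140,1,0
141,0,0
142,1,1
143,0,0
144,0,0
145,1,1
146,0,0
147,1,0
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
158,0,0
159,1,1
160,0,1
161,0,0
162,1,0
163,0,0
164,0,0
165,1,1
166,0,0
167,0,0
168,1,1
169,0,1
170,0,0
171,1,0
172,0,0
173,0,0
174,1,1
175,0,0
176,1,1
177,0,0
178,0,0
179,1,0
180,0,1
181,0,0
182,1,1
183,0,0
184,0,0
185,1,1
186,0,0
187,0,0
188,1,0
189,0,1
190,0,0
191,1,1
192,0,0
193,0,0
194,1,1
195,0,0
196,0,0
197,1,0
198,0,0
199,0,1
200,1,1
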