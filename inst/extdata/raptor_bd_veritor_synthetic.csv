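order,reference,index,day
1,0,0,1
2,0,0,1
3,1,1,1
4,0,0,1
5,0,0,1
6,1,0,1
7,0,0,1
8,0,0,1
9,0,0,1
10,1,1,1
11,0,0,1
12,0,0,1
13,1,1,2
14,0,0,2
15,0,0,2
16,1,1,2
17,0,0,2
18,0,0,2
19,1,0,2
20,0,0,2
21,0,0,2
22,0,0,2
23,1,1,2
24,0,0,2
25,0,0,3
26,1,1,3
27,0,0,3
28,0,0,3
29,1,0,3
30,0,0,3
31,0,0,3
32,1,1,3
33,0,0,3
34,0,0,3
35,0,0,3
36,1,1,3
37,0,0,4
38,0,0,4
39,1,1,4
40,0,0,4
41,0,0,4
42,1,0,4
43,0,0,4
44,0,0,4
45,1,1,4
46,0,0,4
47,0,0,4
48,1,1,4
49,0,0,5
50,0,0,5
51,0,0,5
52,1,1,5
53,0,0,5
54,0,0,5
55,1,0,5
56,0,0,5
57,0,0,5
58,1,1,5
59,0,0,5
60,0,0,5
61,1,1,6
62,0,0,6
63,0,0,6
64,0,0,6
65,1,0,6
66,0,0,6
67,0,0,6
68,1,1,6
69,0,0,6
70,0,0,6
71,1,1,6
72,0,0,6
73,0,0,7
74,1,1,7
75,0,0,7
76,0,0,7
77,0,0,7
78,1,0,7
79,0,0,7
80,0,0,7
81,1,1,7
82,0,0,7
83,0,1,7
84,1,1,7
85,0,0,8
86,0,0,8
87,1,1,8
88,0,0,8
89,0,0,8
90,1,0,8
91,0,0,8
92,0,0,8
93,0,0,8
94,1,1,8
95,0,0,8
96,0,0,8
97,1,1,9
98,0,0,9
99,0,0,9
100,1,1,9
101,0,0,9
102,0,0,9
103,1,0,9
104,0,0,9
105,0,0,9
106,0,0,9
107,1,1,9
108,0,0,9
109,0,0,10
110,1,1,10
111,0,0,10
112,0,0,10
113,1,0,10
114,0,0,10
115,0,0,10
116,1,1,10
117,0,0,10
118,0,0,10
119,0,0,10
120,1,1,10
121,0,0,11
122,0,0,11
123,1,1,11
124,0,0,11
125,0,0,11
126,1,0,11
127,0,0,11
128,0,0,11
129,1,1,11
130,0,0,11
131,0,0,11
132,1,1,11
133,0,0,12
134,0,0,12
135,0,0,12
136,1,1,12
137,0,0,12
138,0,0,12
139,1,0,12
140,0,0,12
141,0,0,12
142,1,1,12
143,0,0,12
144,0,0,12
145,1,1,13
146,0,0,13
147,0,0,13
148,0,0,13
149,1,0,13
150,0,0,13
151,0,0,13
152,1,1,13
153,0,0,13
154,0,0,13
155,1,1,13
156,0,0,13
157,0,0,14
158,1,1,14
159,0,0,14
160,0,0,14
161,0,0,14
162,1,0,15
163,0,0,15
164,0,0,15
165,1,1,15
166,0,0,15
167,0,1,15
168,1,1,15
169,0,0,16
170,1,1,16
171,0,0,16
172,0,0,16
173,1,1,16
174,0,0,16
175,1,0,16
176,0,0,16
177,1,1,16
178,0,0,16
179,1,1,16
180,0,0,16
181,0,0,17
182,1,1,17
183,0,0,17
184,1,1,17
185,0,0,17
186,1,1,17
187,0,0,17
188,1,0,17
189,0,0,17
190,0,0,17
191,1,1,17
192,0,0,17
193,1,1,18
194,0,0,18
195,1,1,18
196,0,0,18
197,1,1,18
198,0,0,18
199,0,0,18
200,1,0,18
201,0,0,18
202,1,1,18
203,0,0,18
204,1,1,18
205,0,0,19
206,1,1,19
207,0,0,19
208,0,0,19
209,1,1,19
210,0,0,19
211,1,1,19
212,0,0,19
213,1,0,19
214,0,0,19
215,1,1,19
216,0,0,19
217,0,0,20
218,1,1,20
219,0,0,20
220,1,1,20
221,0,0,20
222,1,1,20
223,0,0,20
224,1,0,20
225,0,0,20
226,0,0,20
227,1,1,20
228,0,0,20
229,1,1,21
230,0,0,21
231,1,1,21
232,0,0,21
233,1,1,21
234,0,0,21
235,0,0,21
236,1,1,21
237,0,0,21
238,1,0,21
239,0,0,21
240,1,1,21
241,0,0,22
242,1,1,22
243,0,0,22
244,0,0,22
245,1,1,22
246,0,0,22
247,1,1,22
248,0,0,22
249,1,1,22
250,0,0,22
251,1,0,22
252,0,0,22
253,0,0,23
254,1,1,23
255,0,0,23
256,1,1,23
257,0,0,23
258,1,1,23
259,0,0,23
260,1,1,23
261,0,0,23
262,0,0,23
263,1,1,23
264,0,0,23
265,1,0,24
266,0,0,24
267,1,1,24
268,0,0,24
269,1,1,24
270,0,0,24
271,0,0,24
272,1,1,24
273,0,0,24
274,1,1,24
275,0,0,24
276,1,0,25
277,0,0,25
278,1,1,25
279,0,0,25
280,0,0,25
281,1,1,25
282,0,1,25
283,1,1,25
284,0,0,26
285,1,1,26
286,0,0,26
287,1,1,26
288,0,0,26
289,1,0,26
290,0,0,26
291,1,1,26
292,0,0,26
293,1,1,26
294,0,0,26
295,1,1,26
296,0,0,27
297,1,1,27
298,0,0,27
299,0,0,27
300,1,0,27
301,0,0,27
302,1,1,27
303,0,0,27
304,1,1,27
305,0,0,27
306,1,1,27
307,0,0,27
308,1,1,28
309,0,0,28
310,1,0,28
311,0,0,28
312,1,1,28
313,0,0,28
314,1,1,28
315,0,0,28
316,1,1,28
317,0,0,28
318,1,1,28
319,0,0,28
320,1,0,29
321,0,0,29
322,1,1,29
323,0,0,29
324,1,1,29
325,0,0,29
326,1,1,29
327,0,0,29
328,1,1,29
329,0,0,29
330,1,0,29
331,0,0,29
332,0,0,30
333,1,1,30
334,0,0,30
335,1,1,30
336,0,0,30
337,1,1,30
338,0,0,30
339,1,1,30
340,0,0,30
341,1,1,30
342,0,0,30
343,1,0,30
344,0,0,31
345,1,1,31
346,0,0,31
347,1,1,31
348,0,0,31
349,1,1,31
350,0,0,31
351,1,1,31
352,0,0,31
353,1,0,31
354,0,0,31
355,1,1,31
356,0,0,32
357,1,1,32
358,0,0,32
359,1,1,32
360,0,0,32
361,1,1,32
362,0,0,32
363,1,0,32
364,0,0,32
365,0,0,32
366,1,1,32
367,0,0,32
368,1,1,33
369,0,0,33
370,1,1,33
371,0,0,33
372,1,1,33
373,0,0,33
374,1,0,33
375,0,0,33
376,1,1,33
377,0,0,33
378,1,1,33
379,0,0,33
380,1,1,34
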