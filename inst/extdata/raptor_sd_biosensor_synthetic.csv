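order,reference,index,day
1,0,0,1
2,0,0,1
3,1,1,1
4,0,0,1
5,1,1,1
6,0,0,1
7,0,0,1
8,1,1,1
9,0,0,1
10,1,0,1
11,0,0,1
12,0,0,1
13,1,1,2
14,0,0,2
15,1,1,2
16,0,0,2
17,0,0,2
18,1,1,2
19,0,0,2
20,0,0,2
21,1,1,2
22,0,0,2
23,1,1,2
24,0,0,2
25,0,0,3
26,1,1,3
27,0,0,3
28,1,1,3
29,0,0,3
30,0,0,3
31,1,1,3
32,0,0,3
33,1,0,3
34,0,0,3
35,0,0,3
36,1,1,3
37,0,0,4
38,1,1,4
39,0,0,4
40,0,0,4
41,1,1,4
42,0,0,4
43,0,0,4
44,1,1,4
45,0,0,4
46,1,1,4
47,0,0,4
48,0,0,4
49,1,1,5
50,0,0,5
51,1,1,5
52,0,0,5
53,0,0,5
54,1,1,5
55,0,0,5
56,1,0,5
57,0,0,5
58,0,0,5
59,1,1,5
60,0,0,5
61,0,0,6
62,1,1,6
63,0,0,6
64,1,1,6
65,0,0,6
66,0,0,6
67,1,1,6
68,0,1,6
69,1,1,6
70,0,0,6
71,0,0,6
72,1,1,6
73,0,0,7
74,1,1,7
75,0,0,7
76,0,0,7
77,1,1,7
78,0,0,7
79,0,0,7
80,1,0,7
81,0,0,7
82,1,1,7
83,0,0,7
84,0,0,7
85,1,1,8
86,0,0,8
87,1,1,8
88,0,0,8
89,0,0,8
90,1,1,8
91,0,0,8
92,1,1,8
93,0,0,8
94,0,0,8
95,1,1,8
96,0,0,8
97,0,0,9
98,1,1,9
99,0,0,9
100,1,1,9
101,0,0,9
102,0,0,9
103,1,0,9
104,0,0,9
105,1,1,9
106,0,0,9
107,0,0,9
108,1,1,9
109,0,0,10
110,1,1,10
111,0,0,10
112,0,0,10
113,1,1,10
114,0,0,10
115,1,1,10
116,0,0,10
117,0,0,10
118,1,1,10
119,0,0,10
120,0,0,10
121,1,1,11
122,0,0,11
123,1,1,11
124,0,0,11
125,0,0,11
126,1,0,11
127,0,0,11
128,1,1,12
129,0,0,12
130,0,0,12
131,1,1,12
132,0,0,12
133,1,1,12
134,0,0,12
135,0,1,12
136,1,1,12
137,0,0,13
138,0,0,13
139,1,1,13
140,0,0,13
141,1,0,13
142,0,0,13
143,0,0,13
144,1,1,13
145,0,0,13
146,0,0,13
147,1,1,13
148,0,0,13
149,0,0,14
150,1,1,14
151,0,0,14
152,1,0,14
153,0,0,14
154,0,0,14
155,1,1,14
156,0,0,14
157,0,0,14
158,1,1,14
159,0,0,14
160,0,0,14
161,1,1,15
162,0,0,15
163,1,0,15
164,0,0,15
165,0,0,15
166,1,1,15
167,0,0,15
168,0,0,15
169,1,1,15
170,0,0,15
171,0,0,15
172,1,1,15
173,0,0,16
174,1,1,16
175,0,0,16
176,0,0,16
177,1,0,16
178,0,0,16
179,0,0,16
180,1,1,16
181,0,0,16
182,0,0,16
183,1,1,16
184,0,0,16
185,1,1,17
186,0,0,17
187,0,0,17
188,1,0,17
189,0,0,17
190,0,0,17
191,1,1,17
192,0,0,17
193,0,0,17
194,1,1,17
195,0,0,17
196,1,1,17
197,0,0,18
198,0,0,18
199,1,0,18
200,0,0,18
201,0,0,18
202,1,1,18
203,0,0,18
204,1,1,18
205,0,1,18
206,0,0,18
207,1,1,18
208,0,0,18
209,0,0,19
210,1,0,19
211,0,0,19
212,0,0,19
213,1,1,19
214,0,0,19
215,1,1,19
216,0,0,19
217,0,0,19
218,1,1,19
219,0,0,19
220,0,0,19
221,1,0,20
222,0,0,20
223,0,0,20
224,1,1,20
225,0,0,20
226,1,1,20
227,0,0,20
228,0,0,20
229,1,1,20
230,0,0,20
231,0,0,20
232,1,0,20
233,0,0,21
234,0,0,21
235,1,1,21
236,0,0,21
237,1,1,21
238,0,0,21
239,0,0,21
240,1,1,21
241,0,0,21
242,0,0,21
243,1,1,21
244,0,0,21
245,0,0,22
246,1,0,22
247,0,0,22
248,1,1,22
249,0,0,22
250,0,0,22
251,1,1,22
252,0,0,22
253,0,0,22
254,1,1,22
255,0,0,22
256,0,0,22
257,1,0,23
258,0,0,23
259,1,1,23
260,0,0,23
261,0,0,23
262,1,1,23
263,0,0,23
264,0,0,23
265,1,1,24
266,0,0,24
267,0,0,24
268,1,0,24
269,0,0,24
270,1,1,24
271,0,0,24
272,0,1,24
273,1,1,24
274,0,0,25
275,0,0,25
276,1,1,25
277,0,0,25
278,0,0,25
279,1,1,25
280,0,0,25
281,0,0,25
282,1,0,25
283,0,0,25
284,0,0,25
285,1,1,25
286,0,0,26
287,0,0,26
288,1,1,26
289,0,0,26
290,0,0,26
291,1,1,26
292,0,0,26
293,0,0,26
294,1,1,26
295,0,0,26
296,0,0,26
297,1,1,26
298,0,0,27
299,0,0,27
300,1,0,27
301,0,0,27
302,0,0,27
303,1,1,27
304,0,0,27
305,0,0,27
306,1,1,27
307,0,0,27
308,1,1,27
309,0,0,27
310,0,0,28
311,1,1,28
312,0,0,28
313,0,0,28
314,1,1,28
315,0,0,28
316,0,0,28
317,1,0,28
318,0,0,28
319,0,0,28
320,1,1,28
321,0,0,28
322,0,0,29
323,1,1,29
324,0,0,29
325,0,0,29
326,1,1,29
327,0,0,29
328,0,0,29
329,1,1,29
330,0,0,29
331,0,0,29
332,1,1,29
333,0,0,29
334,0,0,30
335,1,0,30
336,0,0,30
337,0,0,30
338,1,1,30
339,0,0,30
340,0,0,30
341,1,1,30
342,0,0,30
343,0,0,30
344,1,1,30
345,0,0,30
346,0,0,31
347,1,1,31
348,0,0,31
349,0,0,31
350,1,0,31
351,0,0,31
352,0,0,31
353,1,1,31
354,0,0,31
355,0,0,31
356,1,1,31
357,0,0,31
358,0,0,32
359,1,1,32
360,0,0,32
361,0,0,32
362,1,1,32
363,0,0,32
364,0,0,32
365,1,1,32
366,0,0,32
367,0,0,32
368,1,0,32
369,0,0,32
370,0,0,33
371,1,1,33
372,0,0,33
373,0,0,33
374,1,1,33
375,0,0,33
376,0,0,33
377,1,1,33
378,0,0,33
379,1,1,33
380,0,0,33
381,0,0,33
382,1,1,34
383,0,0,34
384,0,0,34
385,1,0,34
386,0,0,34
387,0,0,34
388,1,1,34
389,0,0,34
390,0,0,34
391,1,1,34
392,0,0,34
393,0,0,34
394,1,1,35
395,0,0,35
396,0,0,35
397,1,1,35
398,0,0,35
399,0,0,35
400,1,1,35
401,0,0,35
402,0,0,35
403,1,0,35
404,0,0,35
405,0,0,35
406,1,1,36
407,0,0,36
408,0,0,36
409,1,1,36
410,0,0,36
411,0,0,36
412,1,1,37
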