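age,qx
40,0.00184667729152155
41,0.00196607395954373
42,0.00209604691106324
43,0.00223753143633831
44,0.00239154524542862
45,0.00255919567734586
46,0.00274168752977266
47,0.0029403315609029
48,0.00315655371888257
49,0.00339190515849275
50,0.00364807310910387
51,0.00392689266254831
52,0.00423035955438467
53,0.00456064401705802
54,0.00492010578866586
55,0.00531131036638421
56,0.00573704659905383
57,0.00620034571891126
58,0.00670450191789651
59,0.00725309457928514
60,0.00785001228045534
61,0.00849947868726353
62,0.00920608046457572
63,0.00997479733076523
64,0.0108110343861638
65,0.0117206568462097
66,0.0127100273089729
67,0.0137860456833748
68,0.014956191898188
69,0.0162285715021108
70,0.0176119642510711
71,0.0191158757594652
72,0.0207505922661653
73,0.0225272385325468
74,0.0244578388469595
75,0.0265553810562629
76,0.0288338834782258
77,0.0313084644664603
78,0.0339954142994631
79,0.0369122689443127
80,0.040077885100261
81,0.043512515754154
82,0.047237885274224
83,0.0512772628268852
84,0.055655532617997
85,0.0603992591306838
86,0.0655367451511805
87,0.0710980799374039
88,0.0771151743874824
89,0.0836217795035816
90,0.090653483817568
91,0.098247684748855
92,0.106443528103524
93,0.115281809103764
94,0.12480482746942
95,0.135056188177601
96,0.14608053862938
97,0.157923232093808
98,0.170629906531694
99,0.184245967295372
100,0.198815961846536
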