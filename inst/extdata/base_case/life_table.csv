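age,qx
50,0.000711
51,0.000813
52,0.000930
53,0.001063
54,0.001215
55,0.001389
56,0.001588
57,0.001815
58,0.002075
59,0.002372
60,0.002712
61,0.003100
62,0.003543
63,0.004051
64,0.004631
65,0.005294
66,0.006051
67,0.006918
68,0.007908
69,0.009040
70,0.010334
71,0.011814
72,0.013505
73,0.015438
74,0.017648
75,0.020175
76,0.023063
77,0.026365
78,0.030139
79,0.034453
80,0.039386
81,0.045024
82,0.051470
83,0.058838
84,0.067261
85,0.076890
86,0.087898
87,0.100481
88,0.114866
89,0.131310
90,0.150108
91,0.171597
92,0.196163
93,0.224245
94,0.256348
95,0.293046
96,0.334998
97,0.382956
98,0.437779
99,0.500451
100,0.572095
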