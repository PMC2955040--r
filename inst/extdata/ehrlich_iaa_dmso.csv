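time,weight
9,0.21
13,0.39
17,0.49
21,0.65
29,0.89
33,1.13
37,1.49
40,1.89
43,2.31
49,3.05
55,4.05
57,4.51
60,4.96
66,5.91
72,6.86
74,7.09
78,7.21
82,7.35
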