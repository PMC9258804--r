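"age","q"
50,0.00370000000000004
51,0.00408833591034252
52,0.00451733738659021
53,0.00499124237236992
54,0.00551472594155666
55,0.00609294438376207
56,0.00673158351229464
57,0.00743691154838444
58,0.00821583695314942
59,0.00907597159419105
60,0.0100256996457023
61,0.0110742526281881
62,0.012231790994582
63,0.0135094926615335
64,0.0149196488652665
65,0.0164757676874091
66,0.0181926855435409
67,0.0200866868510882
68,0.0221756319877253
69,0.0244790935096386
70,0.0270185004124798
71,0.0298172899767175
72,0.032901066431743
73,0.0362977652859706
74,0.0400378216876838
75,0.0441543405857038
76,0.0486832657300793
77,0.0536635436687795
78,0.059137277832873
79,0.0651498665347547
80,0.0717501172062862
81,0.078990327452284
82,0.086926321469342
83,0.0956174280672708
84,0.105126383928815
85,0.115519142868951
86,0.126864568750092
87,0.139233986452539
88,0.152700562018734
89,0.167338479979186
90,0.183221883205832
91,0.200423538809307
92,0.219013193113032
93,0.239055580262028
94,0.260608053388583
95,0.283717815465544
96,0.308418740200152
97,0.334727792849537
98,0.362641088004308
99,0.392129657412282
100,1
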