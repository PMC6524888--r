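"age","qx_male","qx_female"
0,0.000229973552027696,0.000163486634603416
1,0.000232962625646205,0.000164891298979231
2,0.000236249576602399,0.000166442139286516
3,0.000239864088852126,0.000168154367011897
4,0.000243838804168228,0.000170044776534706
5,0.000248209616819484,0.000172131909829787
6,0.000253015997595307,0.000174436238303044
7,0.000258301350100631,0.000176980363544743
8,0.000264113402527855,0.000179789238966666
9,0.000270504638438362,0.000182890414494041
10,0.000277532770433075,0.000186314306710123
11,0.000285261260976721,0.000190094497100279
12,0.000293759895065748,0.000194268061315062
13,0.000303105409891868,0.000198875932677756
14,0.000313382187168143,0.00020396330349548
15,0.000324683014340743,0.000209580068101012
16,0.000337109921531353,0.000215781311963648
17,0.00035077510172743,0.000222627851651835
18,0.000365801922484921,0.000230186830932344
19,0.000382326038221859,0.000238532378833423
20,0.000400496613080503,0.000247746336106469
21,0.000420477665315055,0.00025791905718453
22,0.000442449545247969,0.000269150295473475
23,0.000466610560017622,0.000281550180618706
24,0.000493178759642054,0.00029524029728667
25,0.000522393900350471,0.000310354875985519
26,0.000554519602694037,0.000327042107532205
27,0.00058984572366505,0.000345465593975969
28,0.000628690963926704,0.000365805950103271
29,0.000671405733317254,0.000388262571105358
30,0.000718375300038931,0.000413055583590394
31,0.000770023251410845,0.00044042799888766
32,0.00082681529675821,0.000470648089532566
33,0.000889263445959743,0.000504012011959376
34,0.000957930600391732,0.00054084670078336
35,0.00103343559652924,0.000581513062639982
36,0.0011164587462954,0.000626409500396941
37,0.00120774792243394,0.000675975801683104
38,0.00130812524173685,0.00073069742911358
39,0.0014184944039094,0.000791110253366201
40,0.00153984874924373,0.000857805774404086
41,0.00167328010411116,0.000931436880679204
42,0.00181998848961717,0.0010127242011303
43,0.00198129277561188,0.00110246311023277
44,0.00215864236964081,0.00120153145232038
45,0.00235363003838862,0.0013108980579053
46,0.00256800596772955,0.00143163213183239
47,0.00280369317666973,0.00156491360084532
48,0.00306280441026496,0.00171204451656981
49,0.00334766064702396,0.00187446161907434
50,0.00366081136734664,0.00205375017609477
51,0.00400505674118745,0.0022516592237477
52,0.00438347190531729,0.00247011834614319
53,0.00479943351322254,0.00271125614377477
54,0.00525664875373011,0.00297742055393191
55,0.00575918704772305,0.00327120120065438
56,0.00631151464565105,0.0035954539669244
57,0.00691853236166184,0.00395332799783799
58,0.00758561669278535,0.00434829536034731
59,0.00831866458325259,0.00478418360272514
60,0.00912414210421009,0.0052652114750229
61,0.0100091373271303,0.00579602809025848
62,0.010981417674285,0.00638175582460554
63,0.0120494920307256,0.00702803727305712
64,0.0132226778980362,0.00774108659442807
65,0.0145111738591528,0.00852774559546177
66,0.0159261376039009,0.00939554491741301
67,0.0174797697343273,0.0103527706987169
68,0.0191854035246632,0.0114085370929157
69,0.0210576007495833,0.012572865020246
70,0.0231122536124339,0.0138567675221565
71,0.0253666926976779,0.0152723420680141
72,0.0278398007335179,0.0168328701293065
73,0.0305521317751629,0.0185529242850131
74,0.0335260351991137,0.0204484830479919
75,0.0367857836256632,0.022537053500773
76,0.0403577035508156,0.0248378016935632
77,0.0442703070590751,0.027371690579825
78,0.0485544224927935,0.0301616250363823
79,0.0532433213585941,0.0332326032249263
80,0.05837283804238,0.0366118731876469
81,0.0639814780664953,0.0403290931171969
82,0.070110509640528,0.0444164931840525
83,0.0768040321165192,0.0489090361243436
84,0.0841090136474241,0.0538445729682382
85,0.0920752888556349,0.0592639893012887
86,0.10075550564332,0.0652113362759902
87,0.110205008424456,0.0717339392052579
88,0.120481643049195,0.0788824749519459
89,0.131645466562511,0.0867110074605738
90,0.143758342753807,0.0952769686470838
91,0.156883402308392,0.104641069467998
92,0.171084344403795,0.11486712334592
93,0.186424554995864,0.12602176127104
94,0.202966016068674,0.138174014897515
95,0.220767980113519,0.151394740922394
96,0.239885385479587,0.165755857144247
97,0.26036699152368,0.181329358094148
98,0.282253218299341,0.198186076351965
99,0.305573684579747,0.216394155057863
100,1,1
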