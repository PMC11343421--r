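"age","sex","annual_qx","cv_share"
50,"male",0.00448357842554159,0.42004439811622
51,"male",0.004906121324048,0.416043342738842
52,"male",0.00539727559689529,0.409858669048803
53,"male",0.0058335358035162,0.408914565522657
54,"male",0.00651720969411018,0.403700646537972
55,"male",0.0071497742313581,0.397322168209679
56,"male",0.00784755650083258,0.393240638037105
57,"male",0.00870978273333711,0.392579994627046
58,"male",0.00961394101309976,0.384198815787777
59,"male",0.0105561013546897,0.384198815787777
60,"male",0.0114131978704286,0.376351448017786
61,"male",0.0124199525778713,0.375804838067049
62,"male",0.0138355468995865,0.371352742882935
63,"male",0.0149036325714339,0.368863527101854
64,"male",0.0167478090373817,0.36634448171611
65,"male",0.0183404348516868,0.359933381741035
66,"male",0.019940489157739,0.353287153753567
67,"male",0.0219690917831522,0.352941716064128
68,"male",0.0243594522934497,0.346044443352691
69,"male",0.0265793396281522,0.340469429644263
70,"male",0.0297876000541911,0.338890924175873
71,"male",0.0319663974977019,0.336560721007073
72,"male",0.0350594364898444,0.335675486229257
73,"male",0.0392494401179789,0.32758737450333
74,"male",0.042952421005784,0.322103320618253
75,"male",0.046291502883643,0.322103320618253
76,"male",0.0512479906328951,0.316081660121178
77,"male",0.0568163348382803,0.309851017641198
78,"male",0.060830791906885,0.303424365598571
79,"male",0.0677064899824434,0.302822033803325
80,"male",0.0746962507702501,0.29930836342398
81,"male",0.0803128353851543,0.298091513044676
82,"male",0.087658576149843,0.291608416977892
83,"male",0.0954443880944746,0.288359212256969
84,"male",0.10527924298692,0.284416371314935
85,"male",0.115172222473797,0.282302830304421
86,"male",0.126223034506793,0.27229703852968
87,"male",0.139366496585597,0.271961095584096
88,"male",0.150158750943532,0.268901839798582
89,"male",0.164046754789685,0.266433398505009
90,"male",0.180347476344925,0.257852991562709
91,"male",0.193949930906865,0.256964345559171
92,"male",0.215363465904374,0.246419473417212
93,"male",0.236793493003807,0.246419473417212
94,"male",0.250662145373689,0.24330621594947
95,"male",0.273639455856216,0.242200084551097
96,"male",0.298537869857619,0.230614659865353
97,"male",0.318740461688409,0.230614659865353
98,"male",0.343745769364441,0.228107829594546
99,"male",0.370666159076944,0.223230028399752
100,"male",0.402541271657599,0.2231779563958
50,"female",0.00305600268266792,0.423404820544696
51,"female",0.00329771113883692,0.412814914999524
52,"female",0.00363468323835703,0.412814914999524
53,"female",0.00399690024750476,0.411423549802047
54,"female",0.00433828690399196,0.40159127693874
55,"female",0.00485939045484585,0.400025155686499
56,"female",0.00533265564974539,0.396136910688383
57,"female",0.00591384906767578,0.391993956101451
58,"female",0.00635633040894157,0.384710091229087
59,"female",0.00700662568815835,0.383916996966264
60,"female",0.00768316452941042,0.381073392420997
61,"female",0.00854225405861953,0.378757311539863
62,"female",0.00941141420622038,0.372526087448203
63,"female",0.010243465226895,0.369153615468566
64,"female",0.0112335821162539,0.364244397273035
65,"female",0.0123319906707167,0.359055747964275
66,"female",0.0133563903676917,0.355346917243946
67,"female",0.0150560773427353,0.353113143532877
68,"female",0.0164439990597803,0.349831564772063
69,"female",0.0177468119797916,0.345106943184199
70,"female",0.019715008671582,0.338828259081352
71,"female",0.0218096368980305,0.332987148103307
72,"female",0.024383081209674,0.328909780167929
73,"female",0.0270331708202221,0.323949117096572
74,"female",0.0288151879241612,0.323898859513973
75,"female",0.0314761367786188,0.320858468735958
76,"female",0.0348657270527559,0.315798818906131
77,"female",0.0380775477777198,0.310891478154721
78,"female",0.0420858150543426,0.310891478154721
79,"female",0.046461445317741,0.304417110985672
80,"female",0.0500381476422448,0.301822400720526
81,"female",0.0560106093685835,0.295765030697307
82,"female",0.0613067015422469,0.289494716198599
83,"female",0.0671725759986713,0.287618262234294
84,"female",0.0730172879802693,0.281918213703244
85,"female",0.079977181420411,0.27686804972255
86,"female",0.0875877132785212,0.275395865796532
87,"female",0.0950204890036026,0.270332019734997
88,"female",0.104796150293399,0.269408412867546
89,"female",0.113380451157227,0.263708900840504
90,"female",0.126370679226282,0.260385503613612
91,"female",0.137281179208171,0.256390084168538
92,"female",0.152745841659485,0.254369932484913
93,"female",0.166021223640624,0.250402306599367
94,"female",0.17707955015847,0.247217225221145
95,"female",0.192993095307194,0.241762901952586
96,"female",0.21091342120224,0.235796980488652
97,"female",0.22780770762536,0.230668879425922
98,"female",0.248354393086512,0.229647703764108
99,"female",0.274212747207296,0.2234332902244
100,"female",0.296420913539245,0.219419686264596
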