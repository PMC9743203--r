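# protocol=poisson
# rate=0.001
# model=synthetic_inverse_gaussian
# n=200
# censored=0
tau_ps,censored,resets
176.024377140343404,0,NA
939.458434908164463,0,NA
881.893000715012363,0,NA
400.872678159319548,0,NA
138.381750998486041,0,NA
116.768469275784810,0,NA
1178.417608074932787,0,NA
2354.374260569265061,0,NA
126.995682521052913,0,NA
145.254668633106121,0,NA
76.306598577006298,0,NA
4165.134421645575458,0,NA
219.760937609568373,0,NA
367.150014499276040,0,NA
22.290828556575434,0,NA
1343.326540960015336,0,NA
189.776074699155743,0,NA
561.628489712084615,0,NA
81.722048135809018,0,NA
271.182990958305936,0,NA
141.713855221027643,0,NA
1396.902920937755425,0,NA
161.625252865670518,0,NA
1526.242150609766213,0,NA
460.849618953897675,0,NA
964.159942074712262,0,NA
4134.136965519844125,0,NA
277.989742566060158,0,NA
53.047782892495889,0,NA
1244.101539657926651,0,NA
98.097638364840350,0,NA
808.700030891267602,0,NA
1205.780086589190660,0,NA
130.369712015065488,0,NA
382.664491390252579,0,NA
4457.350896832451326,0,NA
515.569875075797199,0,NA
1403.723055210334223,0,NA
421.289556757359151,0,NA
957.732333892181941,0,NA
206.694230917629739,0,NA
327.852003010221097,0,NA
354.828691587861670,0,NA
283.768907126939666,0,NA
373.609066379798037,0,NA
711.539291235474138,0,NA
293.999691407763578,0,NA
285.711816548609931,0,NA
2102.334751886676258,0,NA
58.814567571673251,0,NA
346.834461846560771,0,NA
982.840692777773938,0,NA
296.146427774486938,0,NA
165.065164352704869,0,NA
279.739935935141148,0,NA
98.793093979094010,0,NA
716.209115160631768,0,NA
257.142485921744537,0,NA
171.474931678748362,0,NA
1067.338778096395117,0,NA
82.870286879326159,0,NA
981.589035156289242,0,NA
1269.144844835374670,0,NA
520.299559809369839,0,NA
78.385031813072601,0,NA
773.316041835471196,0,NA
55.952846612204667,0,NA
264.679199141902927,0,NA
387.689397150773630,0,NA
50.232995222275349,0,NA
143.344907132383469,0,NA
129.711354772882714,0,NA
557.985589833720837,0,NA
860.367548130658179,0,NA
759.241080463181561,0,NA
628.084125794955071,0,NA
100.199768710272110,0,NA
278.553513730317263,0,NA
162.485262476917796,0,NA
1281.776650881285605,0,NA
124.097442796291034,0,NA
173.563704941147080,0,NA
1209.128948998064516,0,NA
70.173133485452126,0,NA
1664.870447927067971,0,NA
135.145481434948067,0,NA
791.889268801679691,0,NA
603.510105792696663,0,NA
608.504992253638534,0,NA
225.104849121998996,0,NA
1168.970572427676643,0,NA
1779.252389839973375,0,NA
268.999499072122262,0,NA
1213.730001713050569,0,NA
351.080243863268834,0,NA
52.580629439784389,0,NA
136.994962891157229,0,NA
134.627558935099842,0,NA
1106.837318269538855,0,NA
139.578419457752261,0,NA
1352.193014743412732,0,NA
289.911151906796476,0,NA
161.517927848522959,0,NA
379.236806380707719,0,NA
120.733708059844957,0,NA
480.825601050834052,0,NA
672.593467301068586,0,NA
138.983263139866267,0,NA
145.604105301134894,0,NA
142.129626782356809,0,NA
116.623498396245850,0,NA
144.587650858840789,0,NA
270.638200924597186,0,NA
3028.203323907792765,0,NA
2268.169082978565257,0,NA
65.206980708428091,0,NA
60.782271091677103,0,NA
362.177125967930806,0,NA
592.395474082488363,0,NA
773.705599809374121,0,NA
2521.958059359039908,0,NA
1688.206141551457222,0,NA
115.165947022992441,0,NA
1020.274018352654707,0,NA
266.061743928318037,0,NA
2414.306733415002782,0,NA
154.927368533223216,0,NA
151.127903612499722,0,NA
1179.636325249979564,0,NA
368.884112995719761,0,NA
179.021002873195357,0,NA
1037.112295758713572,0,NA
294.648204201835370,0,NA
1008.622737917693030,0,NA
74.847686812288885,0,NA
216.148163499563452,0,NA
130.950658307296635,0,NA
854.041061721138931,0,NA
830.058237846679845,0,NA
553.678037246008103,0,NA
1043.374831243758763,0,NA
123.586216574833543,0,NA
232.284530224066657,0,NA
70.992071931600549,0,NA
2373.376416288249857,0,NA
257.667616328052191,0,NA
71.573563415161516,0,NA
2170.211382032870461,0,NA
206.820201630475822,0,NA
159.945115720307967,0,NA
142.189295057877189,0,NA
663.905680833506267,0,NA
40.199797858034799,0,NA
1518.938441397081078,0,NA
243.236379367457403,0,NA
27.160187419111026,0,NA
319.840742519298146,0,NA
721.602793195917911,0,NA
327.138020193563079,0,NA
1771.682479768717258,0,NA
71.304430631263131,0,NA
1193.606349464072991,0,NA
472.489295167475575,0,NA
85.663178495405191,0,NA
2744.132858715128350,0,NA
303.116542336256316,0,NA
1903.385893161778313,0,NA
72.282863290428395,0,NA
350.721470202107469,0,NA
47.073679421831912,0,NA
1296.169418489032523,0,NA
190.900086493682011,0,NA
389.239117522900870,0,NA
662.204585346898511,0,NA
341.944184792467297,0,NA
138.755227764063420,0,NA
124.265370819894997,0,NA
441.757740240783733,0,NA
1287.967165561066395,0,NA
834.638172547180829,0,NA
273.098499245880930,0,NA
604.193774204355009,0,NA
1869.000006399191307,0,NA
331.204751901977033,0,NA
1816.117532455464470,0,NA
249.104159006297323,0,NA
172.411499072102288,0,NA
2304.519554086258722,0,NA
284.810090642123214,0,NA
333.814321664105137,0,NA
1114.634743367175361,0,NA
161.053598673614488,0,NA
748.815925663401686,0,NA
156.623857167354345,0,NA
117.443649643058961,0,NA
1135.823277114217944,0,NA
120.901284208629022,0,NA
389.983009255930256,0,NA
297.556050480741874,0,NA
66.295955676272570,0,NA
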