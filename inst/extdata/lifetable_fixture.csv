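"age","q_female","q_male"
40,0.000886779965719853,0.00141884794515176
41,0.000970291833795651,0.00155246693407304
42,0.00106166837222837,0.00169866939556539
43,0.00116165023071545,0.00185864036914473
44,0.00127104780910908,0.00203367649457452
45,0.001390747826087,0.0022251965217392
46,0.00152172050642332,0.00243475281027731
47,0.00166502744511527,0.00266404391218443
48,0.00182183021210852,0.00291492833937362
49,0.00199339976736635,0.00318943962778615
50,0.0021811267625962,0.00348980282015393
51,0.00238653281313397,0.00381845250101435
52,0.00261128283134984,0.00417805253015974
53,0.00285719852154392,0.00457151763447027
54,0.00312627314571391,0.00500203703314225
55,0.00342068767987835,0.00547310028780536
56,0.00374282849191013,0.00598852558705621
57,0.00409530668416722,0.00655249069466755
58,0.00448097925770183,0.00716956681232292
59,0.0049029722695938,0.00784475563135008
60,0.00536470617110931,0.00858352987377489
61,0.00586992353206245,0.00939187765129992
62,0.00642271937609879,0.0102763510017581
63,0.00702757437278247,0.0112441189964519
64,0.00768939115552435,0.012303025848839
65,0.00841353405972503,0.0134616544955601
66,0.00920587260322903,0.0147293961651664
67,0.0100728290615195,0.0161165264984313
68,0.0110214305232732,0.0176342888372371
69,0.0120593658482092,0.0192949853571347
70,0.0131950479889033,0.0211120767822453
71,0.0144376821817142,0.0231002914907427
72,0.0157973405595406,0.025275744895265
73,0.0172850437911826,0.0276560700658922
74,0.0189128504090304,0.0302605606544487
75,0.0206939545491247,0.0331103272785995
76,0.0226427928958167,0.0362284686333066
77,0.0247751616978656,0.039640258716585
78,0.0271083448044429,0.0433733516871086
79,0.0296612537588351,0.0474580060141362
80,0.0324545810853719,0.051927329736595
81,0.0355109680120395,0.0568175488192632
82,0.0388551879882519,0.0621683007812031
83,0.0425143474852768,0.068022955976443
84,0.0465181057068972,0.0744289691310355
85,0.0508989149911675,0.081438263985868
86,0.0556922838518331,0.089107654162933
87,0.0609370647914868,0.0974993036663788
88,0.066675769219323,0.106681230750917
89,0.0729549120260467,0.116727859241675
90,0.0798253886088762,0.127720621774202
91,0.0873428874026072,0.139748619844172
92,0.0955683412604926,0.152909346016788
93,0.104568421343595,0.167309474149751
94,0.114416077521812,0.183065724034899
95,0.125191129666789,0.200305807466862
96,0.136980914629405,0.219169463407048
97,0.149880994145914,0.239809590633462
98,0.16399592941063,0.262393487057008
99,0.179440128593446,0.287104205749514
100,0.196338774171705,0.314142038674727
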