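"study_id","year","substance","group","design","baseline_state","regimen","n","count_rem","count_lda","count_mhda","followup_months","trans_rem","trans_lda","trans_mhda"
"Emery",2014,"ETA","CG","RCT","REM","standard",63,55,3,5,10,0.8413,0.0794,0.0794
"Tanaka",2015,"ADA","CG","OC","REM","standard",23,19,2,2,12,0.955,0.0225,0.0225
"Haschka",2016,"TNF","CG","RCT","REM","standard",38,33,5,0,6,0.8684,0.1316,0
"Smolen",2013,"ETA","CG","RCT","LDA","standard",181,134,32,15,12,0.2862,0.6925,0.0214
"Smolen",2014,"ADA","CG","RCT","LDA","standard",96,90,6,0,12,0.5,0.5,0
"van Herwaarden",2015,"ADA, ETA","CG","RCT","LDA","standard",59,48,6,5,9,0.4287,0.5422,0.0291
"Keystone",2016,"ETA","IG","RCT","LDA","standard",47,24,6,17,18,0.1123,0.8156,0.0721
"Kremer",2005,"ABA","IG","RCT","MHDA","standard",99,17,12,70,3,0.1717,0.1212,0.7071
"Westhovens",2006,"INF","IG","RCT","MHDA","standard",663,216,371,76,6,0.1789,0.3364,0.4847
"Emery",2008,"ETA","IG","RCT","MHDA","standard",221,132,38,51,12,0.2034,0.0461,0.7505
"Schiff",2008,"ABA","IG","RCT","MHDA","standard",147,14,17,116,6,0.0488,0.0596,0.8916
"Schiff",2008,"INF","IG","RCT","MHDA","standard",152,20,20,112,6,0.0681,0.0681,0.8638
"Ruubert-Roth",2010,"RITU","IG","RCT","MHDA","standard",314,44,31,239,12,0.037,0.0257,0.9373
"Kim",2012,"ETA","IG","RCT","MHDA","standard",193,82,30,81,4,0.3396,0.119,0.5414
"Kavanaugh",2013,"ADA","IG","RCT","MHDA","standard",466,175,67,224,6,0.2098,0.0747,0.7156
"Smolen",2013,"ETA","CG","RCT","MHDA","standard",757,525,152,80,9,0.3258,0.072,0.6022
"Yoo",2013,"INF","IG","RCT","MHDA","standard",246,46,41,159,4,0.1438,0.1278,0.7284
"Yoo",2013,"INF","CG","RCT","MHDA","standard",249,44,29,176,4,0.1357,0.0887,0.7756
"Dougados",2014,"TOC","IG","RCT","MHDA","standard",277,112,59,106,6,0.2282,0.1129,0.6589
"Horslev-Petersen",2014,"ADA","IG","RCT","MHDA","standard",81,66,5,10,12,0.344,0.0158,0.6402
"Machado",2014,"ETA","IG","RCT","MHDA","standard",269,70,61,138,6,0.1399,0.1207,0.7394
"Nam",2014,"INF","CG","RCT","MHDA","standard",55,22,7,26,4,0.3338,0.0971,0.5847
"Schiff",2014,"ABA, ADA","IG","RCT","MHDA","standard",274,138,51,85,12,0.1606,0.0502,0.7892
"Schiff",2014,"ABA, ADA","CG","RCT","MHDA","standard",269,137,64,68,12,0.163,0.0657,0.7713
"Keystone",2016,"ETA","IG","RCT","MHDA","standard",58,8,9,41,18,0.0244,0.0277,0.9479
"Haschka",2016,"TNF","IG","RCT","REM","tapering",36,29,4,3,3,0.8056,0.1111,0.0833
"Haschka",2016,"TNF","IG","RCT","REM","tapering",27,25,0,2,3,0.9259,0,0.0741
"Smolen",2013,"ETA","IG","RCT","LDA","tapering",175,121,38,16,12,0.2547,0.7216,0.0237
"Emery",2014,"ETA","IG","RCT","REM","withdrawal",65,43,8,14,3,0.6615,0.1231,0.2154
"Nam",2014,"ETA","IG","RCT","REM","withdrawal",40,17,7,16,6,0.6829,0.0917,0.2254
"Tanaka",2015,"ADA","IG","OC","REM","withdrawal",52,25,7,20,12,0.8502,0.0355,0.1143
"Haschka",2016,"TNF","IG","RCT","REM","withdrawal",27,20,4,3,3,0.7407,0.1481,0.1111
"Tanaka",2010,"INF","IG","SA","LDA","withdrawal",102,44,12,46,12,0.1316,0.7292,0.1392
"Smolen",2013,"ETA","IG","RCT","LDA","withdrawal",141,58,26,57,12,0.1241,0.7545,0.1215
"Smolen",2014,"ADA","IG","RCT","LDA","withdrawal",89,67,15,7,12,0.2949,0.6848,0.0203
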