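a,b,c,d,oddsratio,ci_low,ci_high
20,100,980,99900,20.387755102,12.562779149,33.0866723972
10,10,10,10,1,0.28950287109,3.45419717682
6,3,994,99000,199.195171026,49.7481722866,797.591435753
1,1,1,1,1,0.0198425239681,50.3968145184
2,30,5,700,9.33333333333,1.73940885562,50.080871343
291,499,397,233,0.342261348894,0.275513324208,0.425180274978
45,52,437,133,0.263377926421,0.168990156561,0.410485045626
418,380,6,69,12.65,5.43007520172,29.4696655305
229,124,421,26,0.114052563022,0.072551870114,0.17929223756
188,284,314,25,0.0527047636135,0.0337053949131,0.0824138721627
88,207,268,138,0.218905472637,0.158469041411,0.302390962448
25,294,379,295,0.066187424838,0.0428084592923,0.102334334828
263,356,250,198,0.585101123596,0.457831426695,0.747749728113
121,215,311,324,0.58631571076,0.446819285668,0.769362746218
358,280,154,402,3.33756957328,2.61809296911,4.25476512406
193,203,204,475,2.21373031971,1.71304156907,2.86076065923
459,271,271,181,1.13123459648,0.889225996515,1.43910740047
330,64,232,135,3.00040409483,2.13222718219,4.22207577478
414,81,217,485,11.4234511009,8.57405530003,15.2197799626
33,162,436,47,0.021958885491,0.0135840528769,0.0354969651825
108,270,417,352,0.337649880096,0.259195269187,0.439851552409
196,237,467,400,0.708354791785,0.561913269864,0.892960778745
64,174,466,324,0.255734793547,0.185759651437,0.352069376341
229,8,246,175,20.3633130081,9.80236131182,42.302512984
454,104,246,110,1.95200125078,1.43206712234,2.66070550996
205,497,122,438,1.48085232708,1.14374066469,1.9173259134
222,456,487,391,0.390873230304,0.31733520745,0.481452667656
66,69,358,396,1.0580519796,0.733409257182,1.52639741122
10,250,196,467,0.095306122449,0.0495699107036,0.183241342325
341,433,291,165,0.446536987215,0.3519798008,0.566496374217
40,330,245,345,0.170686456401,0.118285083555,0.246302116235
205,191,416,408,1.05265807491,0.828221409639,1.33791400437
344,155,499,214,0.951787445859,0.74259357072,1.21991271917
13,153,179,1,0.000474677766824,6.13913990084e-05,0.00367020439274
320,297,151,485,3.46065511628,2.71829590623,4.40575060516
426,361,498,408,0.966792377265,0.79805885756,1.17120121139
233,58,148,112,3.04007455732,2.08290514113,4.43709755741
321,275,318,229,0.840583190395,0.665155572014,1.06227795376
195,47,30,183,25.3085106383,15.3431296014,41.7464185839
348,448,32,28,0.6796875,0.401603004246,1.1503277933
206,110,134,130,1.81682496608,1.30049385364,2.53815344696
407,165,289,417,3.55916955017,2.81377917423,4.50201920709
16,454,171,455,0.0937733467295,0.0552705890266,0.159098006946
315,153,313,492,3.23623379064,2.54686093015,4.11220299613
262,268,174,138,0.775347400926,0.585462532705,1.02681821388
373,398,318,130,0.383126323441,0.298930361966,0.491036704161
161,466,493,220,0.154175626148,0.121340409898,0.195896187578
335,92,330,249,2.74752964427,2.06958201871,3.64755737047
285,61,386,402,4.8657946148,3.56960059278,6.63266284785
114,488,467,421,0.210596061361,0.165208607904,0.268452725458
323,483,498,471,0.632480231485,0.523565349024,0.764052174126
160,108,491,24,0.0724145734329,0.0449466873129,0.116668674801
310,241,102,254,3.20315678138,2.40927751314,4.25862662568
198,20,313,44,1.39169329073,0.796761253806,2.43085391794
202,190,466,419,0.955929523379,0.753461536632,1.21280411705
119,78,485,9,0.0283108643933,0.0138007013164,0.0580771240768
282,329,326,223,0.586327782647,0.464442464143,0.740199906866
13,42,385,10,0.00803957946815,0.00332206740878,0.0194562090624
444,329,47,461,13.2370173964,9.49495972072,18.4538570679
457,439,101,37,0.381357270123,0.255947250314,0.568216174613
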