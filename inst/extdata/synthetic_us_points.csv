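# Synthetic ultrasound profile points (NOT patient data): 164 points on the
# package's average-eye Limacon with radial Gaussian noise sd 0.1 mm, seed 42.
x_mm,y_mm
12.1370958447147,0
11.9333003093644,0.43824825181942
11.9951618962144,0.88253558927111
11.9706715162451,1.3242330720495
11.8764251638641,1.75719675959039
11.7348243058549,2.17886577641386
11.7816436998837,2.64000635124289
11.4954421175622,3.02160042288348
11.5484727846697,3.49650140270425
11.1835145339657,3.83705723813954
11.1263366073433,4.28279842304608
11.0130199448462,4.71290925727949
10.4627983715729,4.93289576216957
10.3302394470806,5.34551476057616
10.0960530650084,5.70490432109709
9.89975236062514,6.08721803664093
9.54883831170369,6.36481068382761
9.07417573303494,6.53581013386478
8.79893684398812,6.84408282634827
8.77674230829085,7.37620468566648
8.33703240085492,7.54238738266833
7.9072596288752,7.69662585170777
7.68245036510535,8.05933313233364
7.4264449479216,8.39880676996893
7.11218632607385,8.67437186486984
6.61419017723484,8.69253165084455
6.26080683706516,8.89571514275674
5.81532303156722,8.94074974753858
5.5534354952833,9.29311454069521
5.12507013429766,9.34109363424392
4.7906554186232,9.57110428612123
4.41402146701542,9.71133952349122
4.03593958967395,9.84511297408297
3.59401245722859,9.77666200925319
3.23587568209457,9.95570508777262
2.7926773642616,9.79738898363284
2.4258814508502,9.93036834504725
2.03707708967672,9.95132866388475
1.63238607309384,9.80886895833745
1.27164600088994,10.0508079386602
0.885284543451218,10.0515492567196
0.499999999999998,9.96389427014513
0.115536866247055,10.030119795864
-0.254052700542247,9.82165249354949
-0.617903558874104,9.68341961950851
-1.00952648736692,9.77296083814966
-1.35155712569492,9.54713191818247
-1.75817452253622,9.64994662358094
-2.06570221226145,9.33645294466191
-2.44180919881121,9.2957202435608
-2.7702678419512,9.10540339929531
-3.05936675498518,8.83138208044789
-3.47380643183244,8.86431373790718
-3.74945549835163,8.58247778996829
-4.02722868142707,8.32543617657548
-4.32908188999848,8.12285771390205
-4.63348376989971,7.92701623202789
-4.87258558832648,7.63819392587491
-4.94576461017862,7.14417062492042
-5.39381212094614,7.1466660768279
-5.58819247011615,6.8314807337637
-5.85071316014572,6.59880516333145
-6.09322715423794,6.34534486469211
-6.35737341484561,6.11126793971601
-6.38645757409431,5.67921974865704
-6.72400597350291,5.50662045178397
-6.81396902639003,5.14453088858284
-7.02810425110874,4.87515098493666
-7.16302220722164,4.55570724822823
-7.27884366618099,4.2300010962738
-7.24256712881704,3.83358923402815
-7.43748006333481,3.55831373536972
-7.60257085732085,3.26562944245268
-7.54364424873802,2.88892978874274
-7.66013774174192,2.58243230682977
-7.83652305100755,2.29091666410291
-7.91423819504656,1.96900760799797
-7.93445221206341,1.63576561300436
-7.84159682125651,1.28843874002532
-7.8509865180789,0.964080656988391
-8.13318726216745,0.662808847452069
-8.0213681501234,0.326631383227336
-8.00884402291596,-2.73665295916336e-15
-7.98351415099713,-0.325180406825723
-7.8632779698257,-0.642086689859403
-8.02103488212233,-0.983711911112906
-7.90767685283697,-1.29864542760023
-7.8709823841278,-1.62345636524411
-7.93032048777387,-1.97277100950862
-7.85974002006169,-2.29729679895897
-7.84461471808737,-2.64081358894267
-7.58856951572734,-2.90506500532608
-7.60505938337917,-3.26663240856152
-7.57264893596615,-3.61890894345097
-7.23650278179121,-3.83058658450858
-7.13989195312517,-4.15444154992238
-6.98659836055152,-4.45082233790161
-6.81845426165034,-4.73938302549992
-6.79304103046417,-5.12981046509073
-6.67236456200425,-5.46725591446763
-6.53522054880131,-5.80190367064956
-6.33087184005395,-6.08764982610627
-5.97902214902081,-6.23543356838393
-5.96604841353854,-6.71864601370694
-5.56826338619346,-6.80911857068694
-5.3823998949066,-7.1328279416746
-5.10161511219867,-7.34862723627114
-4.86037830103079,-7.62083885053168
-4.60678939682019,-7.88579535003235
-4.3210389777701,-8.10932896596929
-4.02174191656211,-8.31534618247238
-3.72572418211389,-8.53454847417333
-3.38949072788869,-8.67623189104048
-3.06981949561608,-8.8573170718814
-2.70323827205669,-8.91877303656434
-2.41049115553288,-9.19675945133515
-2.0635504550066,-9.32862281524854
-1.78683370307699,-9.77241703485076
-1.34107184836646,-9.49306697767141
-1.00501475753378,-9.74375104332951
-0.616466070684194,-9.67096791808003
-0.248359495961673,-9.74749762755032
0.117963194469218,-9.96682019547127
0.499999999999998,-9.9003360865116
0.884488531387786,-10.0307823855837
1.26809119529375,-10.0045060485897
1.653035237196,-9.98773458516721
2.01915957080776,-9.83532724775287
2.41749874084855,-9.88714481329277
2.83589035459745,-9.98205276671279
3.23753620116205,-9.96174762773033
3.5975138952626,-9.78772608112687
4.00095346912892,-9.74770115452114
4.42964897591159,-9.75011397735563
4.83092436515208,-9.66093165493003
5.10478686221346,-9.30012821355932
5.52585114489544,-9.24238775731698
5.96682277133141,-9.19558303838553
6.24925819014621,-8.87788196831071
6.63593720226321,-8.7234493517814
6.99207483935609,-8.51680042788177
7.29268428156274,-8.23661245548044
7.66430249892426,-8.03896965026837
8.02873954146675,-7.82285140374194
8.32930622943492,-7.53495168828123
8.76130901344039,-7.3624505856171
8.95010814960826,-6.96875288422213
9.25099211457668,-6.6705914043094
9.62908662891283,-6.42125608920868
9.75770497061031,-5.9952290776362
10.1040146446521,-5.70963752232096
10.2184262683602,-5.28471268139032
10.6918609988641,-5.04631189499631
10.7793924565886,-4.60817577841796
10.9619168585402,-4.21653131078417
11.0728799234477,-3.79732206188014
11.355296966525,-3.43536720503952
11.427402159685,-3.00290271493351
11.5825215906493,-2.5934099822176
11.8716547880996,-2.20540248467175
11.8191252387499,-1.74834624272896
11.8013317267969,-1.30468361940554
11.9752284042787,-0.881005204905012
11.9534814647517,-0.439021812893542
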