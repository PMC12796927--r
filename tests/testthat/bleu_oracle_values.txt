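48.2778689978
36.0490575205
30.4848815101
22.3738621556
2.8533204979
50.8220594417
34.6506381236
2.2969441904
29.8407601353
16.6333971470
32.7668982838
36.7168379372
48.9200583161
21.2795828357
5.2999595309
4.1070282829
3.1404711887
18.8121980862
23.7841423001
21.7381216848
6.2183610426
16.8049110578
23.3220032664
40.0809585506
36.1461458155
14.1560296898
56.7057995457
55.7210415716
53.6938648645
37.1364673897
6.1220614474
40.0474053069
17.1815296713
41.0499933469
3.6729121980
24.4510646469
8.9073057580
47.7812123915
25.3280358062
44.6891876628
14.6477054520
3.4621194247
49.0231711730
21.6399539547
13.8071392257
5.0997866946
15.4603416302
43.5117075576
16.9532013758
40.1081278694
72.5518844626
44.6005905210
3.9082754075
4.5637885580
36.8911009718
38.3059781775
45.3429139905
16.6890457944
30.6137647994
4.4348727905
20.0900901039
35.4213699805
2.7774920717
14.4304783746
2.6404861082
2.3043614320
29.1228729668
15.7986240240
11.4431507995
65.5592811170
33.0931672600
56.0952872433
44.2077342186
8.1936420132
23.7832500081
26.3498276375
7.4870599147
27.6568246154
34.5938639364
38.4119425895
21.1184759535
2.8907466013
51.0674337224
4.5852182742
33.4299169173
54.9833874515
29.6069960342
32.6734102353
79.4207144485
4.4345213024
23.3112751667
71.3600787547
6.1519869619
2.7133034385
32.5122774304
56.8472882296
35.2338750707
31.2645590327
32.5035869000
12.3073572696
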