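"x","y"
9.0979,407.7902
10.4488,282.6853
9.4185,350.2661
10.0204,349.4252
10.9904,368.4952
10.3222,352.3041
11.1433,383.4012
9.095,289.9114
10.838,456.1439
12.8633,302.2714
8.4981,402.7985
8.2151,481.7334
8.8212,215.995
10.611,313.3753
11.9744,280.2047
8.0368,369.3025
7.6233,283.8098
9.9466,166.8714
9.6441,194.1735
7.9444,404.0233
10.1676,288.1558
11.2351,196.7591
11.9167,286.1503
9.6374,381.0133
9.6638,450.6499
6.9682,302.3356
11.8586,264.9013
6.9336,215.4419
10.3215,374.0565
10.1436,289.9592
9.8888,334.976
9.3664,328.7004
10.7587,388.8239
9.5972,303.9146
8.9872,349.9265
10.0294,228.264
7.2249,268.5558
9.9856,256.7609
9.3151,243.0718
10.3181,361.3718
11.0445,308.8156
7.7892,349.198
8.5261,397.7306
10.2686,283.4958
9.5444,236.1978
11.7167,343.2932
9.4229,246.1015
10.3088,377.1509
9.8437,288.2312
9.517,348.2085
12.6807,355.0369
11.4786,305.9023
9.9185,414.532
8.9658,382.229
11.4394,303.0306
8.7214,351.455
5.961,363.6294
10.5183,318.109
9.3169,181.2882
9.4929,321.7459
10.4122,292.0389
12.3147,347.0429
9.015,312.6698
7.1423,405.495
11.5647,233.8239
12.6997,373.5395
10.9077,319.0398
10.6672,371.4801
9.1092,365.3065
11.0979,356.8265
9.8693,253.299
9.6491,343.1424
8.9144,372.7349
10.6999,314.3351
11.5818,273.3944
9.5184,378.1029
10.2293,336.1287
8.8256,314.2638
12.616,276.7145
9.7612,252.8416
8.8182,424.7694
8.2232,300.4497
11.0866,354.0312
10.5891,335.2038
10.6169,190.3844
9.687,368.4251
10.918,304.3043
10.1086,355.7895
11.9112,418.021
9.1729,368.2147
9.8654,427.8368
9.4554,287.0624
7.9666,337.8909
8.4018,423.4451
8.8966,267.5649
9.2326,276.3861
9.0378,226.618
11.7517,218.7489
11.317,311.3971
10.1727,362.4627
10.1607,430.0869
11.3644,418.0654
8.4805,249.9949
10.6529,458.8014
9.0263,296.1409
9.5273,336.6313
10.2151,284.0941
9.8337,296.633
9.14,278.4316
9.6606,333.6354
9.2626,293.3128
9.6171,329.7303
9.0213,256.6605
11.0489,278.4001
10.2703,209.1912
11.728,315.4248
8.8902,277.5982
10.4778,507.2337
6.5539,232.9544
9.8362,330.2115
10.0934,223.9033
8.5563,287.2733
10.8853,389.5396
9.0173,297.0076
10.0094,274.7299
8.2223,288.6312
8.6586,269.6681
8.9999,210.9473
7.035,250.8515
9.5528,356.8749
10.0355,405.3863
10.5171,289.5098
11.8442,317.916
10.722,440.7114
9.9091,449.2093
10.4535,246.0944
9.6252,255.8485
10.4669,415.5049
10.2027,331.1954
8.5445,306.4457
9.2934,294.373
9.653,222.4817
10.7655,283.0733
10.4594,291.1701
9.8383,260.2109
8.6495,375.2821
9.6012,289.1314
7.7473,261.4054
11.2307,421.7227
8.0289,303.5696
12.2165,409.7088
10.2871,237.9554
10.1659,365.1716
8.1305,206.613
8.3298,298.0787
7.3835,253.126
9.066,357.2267
11.0318,262.9806
10.2822,279.5056
8.4404,404.697
10.1884,300.8585
10.1572,214.4688
10.8158,320.3314
10.7951,272.3733
12.0454,368.4116
5.3961,325.4497
9.4567,298.4293
11.1173,382.7461
7.3794,337.9655
8.7554,429.324
8.4276,308.5222
11.7975,379.9608
10.3603,209.2549
11.1473,385.342
8.8511,384.3583
10.8873,275.2974
9.8609,218.7862
9.9655,365.2742
12.7192,341.8065
12.4616,270.6958
10.2952,355.7845
10.6937,274.3578
9.3959,349.6036
9.446,262.3609
10.6001,303.6773
13.984,223.7016
9.8358,356.9117
8.3856,323.8766
10.2623,289.5985
9.383,194.1752
8.6444,368.5641
8.6448,331.819
9.0382,310.4105
10.6807,241.2201
10.9758,259.5159
10.2325,362.439
11.8377,343.1995
10.0968,335.9717
8.5474,428.2265
9.5413,324.5981
11.0833,175.9532
12.0936,380.0674
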