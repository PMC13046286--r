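"T1","T2","T3"
-0.3958,0.7854,1.1233
0.6196,-1.4738,-2.4807
-0.0846,0.0209,-0.6105
0.0264,-2.1629,-1.3929
-1.328,-0.6512,-0.9027
-1.4791,-2.5565,-2.5315
1.7312,0.8691,-1.0163
1.544,1.3592,1.6539
1.157,0.6671,1.1991
-0.4802,-1.8287,-3.2839
-0.8159,-0.9142,-0.1
0.1097,-0.8376,1.038
-0.8913,0.1572,0.5127
0.1414,-0.1914,2.2205
0.2249,2.4571,2.9599
-0.2571,-0.3039,1.4648
1.7121,2.9322,5.437
1.5276,1.73,3.265
1.7703,2.7543,4.9413
-0.5416,-0.9081,-1.5404
-1.6991,-0.5502,-0.7957
0.7049,0.7896,1.214
-0.8467,1.5408,2.6376
1.0865,0.4339,0.8801
-0.9923,-0.6199,-1.0863
0.2318,0.9694,0.3051
0.7928,-0.5426,-1.7271
-1.3099,-0.7287,-1.802
1.7554,0.5802,-0.0925
-1.2354,-1.1177,0.4809
1.1704,3.0511,5.271
1.1027,-0.1099,-0.1794
-2.0156,-1.6319,-0.1994
0.0782,-0.2248,-0.5385
-1.7155,-1.0795,-2.965
1.2348,1.3076,0.4148
0.4353,0.289,0.0034
0.9617,-0.5902,-1.0075
0.8147,-0.3097,-1.2633
-0.2892,0.0814,-1.2026
-1.087,-0.24,-0.0094
0.0659,0.0878,1.4505
-0.0331,0.278,-0.5993
0.5849,0.8619,-0.8448
-1.2599,-2.757,-4.8724
-0.0337,0.8604,1.5766
0.8932,1.1507,1.1214
0.9935,2.5719,2.2031
0.0518,0.6436,1.1563
-0.3303,1.7327,0.9155
0.4263,1.8587,2.3474
-0.5556,-0.0687,-0.4487
1.5498,2.5348,2.9239
1.8296,0.2854,-0.5783
-1.3367,-1.7512,-1.5565
-0.9814,-1.7044,-1.6426
0.6221,0.4394,0.5002
-0.1905,0.4259,0.0715
-0.355,-0.2469,-0.2019
0.9544,0.1111,1.0507
-0.5986,0.5648,1.2678
-1.1404,-1.6309,-0.3374
0.3086,1.4499,1.2392
1.0675,2.1195,4.7385
1.5567,2.4438,3.0292
0.5725,-1.3873,-1.8578
0.1797,0.6684,1.2023
1.1672,2.1626,4.1331
-1.0505,-0.743,-2.01
-0.4615,0.1435,1.9569
-0.5832,-0.7796,0.5044
-0.2697,-0.6542,-0.4461
1.7025,1.3007,1.8383
0.4964,-0.2822,-0.0032
1.2909,1.2263,-0.4066
-1.4139,-1.4961,-2.5116
0.8964,2.076,0.2502
-0.1541,0.3161,0.7949
-1.1494,-0.4513,-0.4205
-0.7276,-0.3036,0.6289
-0.3237,-1.4548,-2.0961
0.9414,1.086,1.0124
-0.6437,0.105,-0.2292
0.8373,0.9792,1.8589
-0.0871,0.7944,1.317
-0.5016,-0.8206,-0.9371
-0.5999,-0.4811,-2.6171
-1.6407,-1.3866,-1.2935
-0.1737,1.0628,1.9398
-0.2262,0.4543,0.8113
1.1193,1.5346,1.061
0.8415,1.4552,2.3402
-0.7733,-0.6958,-1.9153
-0.6157,-1.0783,-1.7929
0.4035,1.3918,2.7535
-0.3906,-0.0309,-0.878
-0.2618,-1.6222,-0.823
0.8541,1.1544,-1.3453
-0.5814,0.029,0.3605
0.9283,-0.246,-0.0136
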