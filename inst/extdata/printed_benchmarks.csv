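dataset_id,statistic,mds,sanjay,rp,printed_ratio_mds_sanjay,printed_ratio_rp_sanjay
1,max,3197.8,1000,4069,3.197,4.07
2,max,2711.1,1200,4179,2.259,3.48
3,max,1953,1000,3982,1.953,3.98
4,max,2917.2,1200,5289,2.431,4.4
5,max,3483.5,1400,5045,2.488,3.6
6,max,2925.9,1100,5092,2.659,4.62
7,max,4233,1800,5364,2.351,2.98
8,max,2898,1300,3566,2.229,2.74
9,max,1876.7,1300,4357,1.443,3.35
10,max,4314.1,1500,4262,2.876,2.84
11,max,3543.6,1400,4945,2.531,3.53
12,max,2449.8,1300,4370,1.884,3.36
13,max,3835.2,1500,4747,2.556,3.16
14,max,4153.3,1000,7029,4.153,7.02
15,max,2858.6,1000,6161,2.858,6.16
16,max,3150.4,1200,6732,2.625,5.61
17,max,2497.2,1100,4298,2.27,3.9
18,max,2925.5,1400,4922,2.089,3.51
19,max,3813.3,1300,6719,2.933,5.16
20,max,3700.8,1300,5583,2.846,4.29
21,max,3011.8,1200,5311,2.509,4.42
22,max,3252.4,1000,4447,3.252,4.44
23,max,3381.4,1200,4731,2.817,3.94
24,max,2963.9,1100,6251,2.694,5.68
25,max,3428.3,1600,5919,2.142,3.69
26,max,2712.2,1200,5385,2.26,4.48
27,max,3679.7,1500,4886,2.453,3.25
28,max,3286,1200,5884,2.738,4.9
29,max,2449.7,1000,5398,2.449,5.3
30,max,4160,1400,3900,2.971,2.78
1,avg,1042.4,540.8,1289.2,NA,2.38
2,avg,1024.4,653.3,1226.5,NA,1.87
3,avg,649.2,537.5,1095.5,NA,2.03
4,avg,897.4,765.3,1637.1,NA,2.13
5,avg,1089.6,806.3,1654.7,NA,2.05
6,avg,1069.4,634,1555.5,NA,2.45
7,avg,1374.4,1010.7,1608.8,NA,1.59
8,avg,949.8,709.4,1111.8,NA,1.56
9,avg,765.9,752.5,1439.5,NA,1.91
10,avg,1011.7,892.9,1376.7,NA,1.54
11,avg,1050.4,882.8,1578.5,NA,1.78
12,avg,1050.3,760,1395.6,NA,1.83
13,avg,1241.7,849.7,1363.1,NA,1.6
14,avg,985.7,613.4,2084.7,NA,3.39
15,avg,1249.6,612.4,1916.6,NA,3.12
16,avg,1034.4,733.8,1791.5,NA,2.44
17,avg,919.5,623,1361.3,NA,2.18
18,avg,1056.8,822.4,1480.3,NA,1.8
19,avg,1117.4,757.5,1912.7,NA,2.52
20,avg,989.5,773.6,1806,NA,2.33
21,avg,1057.5,684.8,1535.2,NA,2.24
22,avg,1412.6,605.7,1440.1,NA,2.37
23,avg,915,712.8,1355.4,NA,1.9
24,avg,824.3,741.1,1944.2,NA,2.62
25,avg,1178.1,1033.5,1943.4,NA,1.88
26,avg,949.2,713.3,1762.9,NA,2.47
27,avg,1114.2,833.6,1519,NA,1.82
28,avg,935.4,611.7,1648,NA,2.69
29,avg,1004.8,561.3,1513.4,NA,2.7
30,avg,1178.4,874.1,1047.5,NA,1.19
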