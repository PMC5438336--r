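compound,pic50_obs,pred_pim1,pred_pim2,pim1_role,pim2_role
1,5.567,6.781,6.161,test,train
2,5.996,6.769,5.581,train,test
3,5.787,6.744,4.604,train,train
4,4.657,5.440,6.154,train,train
5,6.458,6.495,7.250,test,train
6,6.010,6.708,7.455,train,test
7,6.983,7.793,6.373,train,train
8,7.229,7.967,7.388,test,train
9,7.431,7.791,7.708,test,test
10,7.677,7.781,7.446,train,train
11,6.644,7.996,8.308,train,test
12,6.717,6.622,7.265,train,train
13,7.376,7.870,7.252,train,train
14,7.920,8.049,7.379,train,train
15,8.000,7.844,7.016,train,train
16,8.221,8.398,7.487,train,train
17,7.744,8.148,7.039,train,train
18,7.657,7.638,7.186,train,train
19,8.000,8.000,7.334,train,train
20,7.387,7.756,6.475,train,train
21,6.943,7.965,7.206,train,train
22,7.552,7.689,8.003,train,test
23,7.769,8.524,8.223,test,test
24,7.602,8.408,5.947,test,train
25,5.889,7.578,7.268,train,train
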