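year,variable,level,xbar,beta,elasticity,conc_index,percent,consistent
2005,age,20-24,0.1855,0.007,0.006,0.031,0.068,1
2005,age,25-29,0.1660,-0.022,-0.015,-0.0004,0.003,1
2005,age,30-34,0.1326,-0.035,-0.019,-0.035,0.263,1
2005,age,35-39,0.1152,-0.010,-0.005,-0.027,0.051,1
2005,age,40-44,0.0866,0.011,0.004,-0.019,-0.028,1
2005,age,45-49,0.0815,0.005,0.002,-0.010,-0.007,1
2005,sex,men,0.2886,0.074,0.085,-0.019,-0.645,1
2005,residence,urban,0.1730,0.052,0.036,0.547,7.82,1
2005,region,tigray,0.0633,-0.037,-0.009,-0.041,0.154,1
2005,region,afar,0.0104,-0.005,-0.0002,-0.018,0.002,1
2005,region,amhara,0.2489,0.055,0.054,-0.045,-0.975,1
2005,region,oromia,0.3612,-0.031,-0.045,-0.041,0.742,1
2005,region,somali,0.0310,-0.123,-0.015,-0.069,0.415,1
2005,region,benishangul,0.0088,0.009,0.0003,-0.003,-0.0004,1
2005,region,snnpr,0.2117,-0.024,-0.020,0.010,-0.083,1
2005,region,gambela,0.0032,-0.081,-0.001,-0.002,0.001,1
2005,region,harari,0.0028,-0.025,-0.0003,0.006,-0.001,1
2005,region,dire_dawa,0.0051,-0.043,-0.001,0.010,-0.004,1
2005,education,primary,0.2692,0.098,0.102,0.098,4.11,1
2005,education,secondary,0.1301,0.187,0.096,0.308,11.76,1
2005,education,higher,0.0173,0.186,0.013,0.060,0.306,1
2005,marital,never_married,0.3038,0.008,-0.010,0.195,-0.742,1
2005,marital,widowed_divorced,0.0854,-0.004,-0.002,0.008,-0.005,1
2005,religion,catholic,0.0114,0.001,0.00003,0.003,0.00003,1
2005,religion,protestant,0.1862,-0.012,-0.009,0.034,-0.116,1
2005,religion,muslim,0.2841,-0.025,-0.028,-0.242,2.70,1
2005,religion,traditional,0.0242,-0.021,-0.002,-0.029,0.024,1
2005,employment,employed,0.5059,0.010,0.021,0.002,0.014,1
2005,wealth,poorer,0.1885,0.008,0.006,-0.352,-0.881,1
2005,wealth,middle,0.1895,0.001,0.001,-0.068,-0.021,1
2005,wealth,richer,0.1933,0.002,0.002,0.227,0.150,1
2005,wealth,richest,0.2565,0.049,0.051,0.763,15.35,1
2005,newspaper,yes,0.2041,0.030,0.025,0.365,3.56,1
2005,radio,yes,0.4887,0.045,0.087,0.486,16.92,1
2005,tv,yes,0.2317,0.025,0.023,0.468,4.26,1
2005,household_head,female,0.1890,0.009,0.007,0.075,0.200,1
2011,age,20-24,0.1790,0.005,0.003,0.050,0.071,1
2011,age,25-29,0.1858,0.020,0.0150,0.011,0.066,1
2011,age,30-34,0.1206,-0.004,-0.002,0.004,-0.003,1
2011,age,35-39,0.1211,-0.023,-0.011,-0.018,0.080,1
2011,age,40-44,0.0811,-0.013,-0.004,-0.019,0.031,1
2011,age,45-49,0.0735,-0.023,-0.007,-0.036,0.099,1
2011,sex,men,0.4372,0.079,0.145,0.003,0.175,1
2011,residence,urban,0.2330,0.026,0.024,0.643,6.35,1
2011,region,tigray,0.0640,0.082,0.021,-0.010,-0.091,1
2011,region,afar,0.0084,-0.007,-0.0002,-0.008,0.001,1
2011,region,amhara,0.2695,0.078,0.085,-0.114,-4.08,1
2011,region,oromia,0.3732,0.071,0.106,-0.019,-0.841,1
2011,region,somali,0.0196,-0.114,-0.009,-0.011,0.042,1
2011,region,benishangul,0.0107,0.110,0.005,-0.006,-0.012,1
2011,region,snnpr,0.1891,0.116,0.088,-0.033,-1.21,1
2011,region,gambela,0.0044,0.026,0.0004,0.003,0.0005,1
2011,region,harari,0.0030,-0.031,-0.0004,0.007,-0.001,1
2011,region,dire_dawa,0.0042,0.049,0.001,0.009,0.003,1
2011,education,primary,0.4459,0.116,0.203,0.079,6.65,1
2011,education,secondary,0.0820,0.180,0.057,0.172,4.10,1
2011,education,higher,0.0568,0.212,0.048,0.166,3.29,1
2011,marital,never_married,0.3428,0.010,0.013,0.173,0.937,1
2011,marital,widowed_divorced,0.0725,-0.024,-0.007,0.007,-0.020,1
2011,religion,catholic,0.0102,-0.006,-0.0002,0.001,-0.0001,1
2011,religion,protestant,0.2080,-0.008,-0.006,-0.017,0.045,1
2011,religion,muslim,0.2857,-0.041,-0.046,-0.086,1.64,1
2011,religion,traditional,0.0194,-0.020,-0.002,-0.029,0.019,1
2011,employment,employed,0.7397,0.020,0.059,-0.025,-0.610,1
2011,wealth,poorer,0.1843,0.012,0.009,-0.346,-1.24,1
2011,wealth,middle,0.1869,0.041,0.031,-0.070,-0.908,1
2011,wealth,richer,0.2008,0.052,0.042,0.239,4.18,1
2011,wealth,richest,0.2535,0.082,0.082,0.751,25.67,1
2011,newspaper,yes,0.2748,0.050,0.054,0.362,8.22,1
2011,radio,yes,0.6410,0.052,0.134,0.313,17.52,1
2011,tv,yes,0.5138,0.029,0.060,0.412,10.37,1
2011,household_head,female,0.1937,0.0002,0.0001,0.086,0.004,1
2011,tested,yes,0.3981,0.067,0.106,0.334,14.83,1
2016,age,20-24,0.1702,-0.001,-0.001,0.010,-0.004,1
2016,age,25-29,0.1808,-0.013,-0.010,0.011,-0.053,1
2016,age,30-34,0.1458,0.008,0.005,-0.011,-0.025,1
2016,age,35-39,0.1216,0.017,0.008,-0.015,-0.062,1
2016,age,40-44,0.0915,-0.023,-0.008,-0.013,0.055,1
2016,age,45-49,0.0720,0.006,0.002,-0.013,-0.011,1
2016,sex,men,0.4253,0.117,0.210,-0.003,-0.316,0
2016,residence,urban,0.2118,-0.002,-0.002,0.601,-0.510,1
2016,region,tigray,0.0673,0.015,0.004,-0.022,-0.044,1
2016,region,afar,0.0077,-0.049,-0.001,-0.013,0.010,1
2016,region,amhara,0.2429,0.038,0.038,-0.015,-0.269,1
2016,region,oromia,0.3705,-0.007,-0.011,-0.029,0.157,1
2016,region,somali,0.0279,-0.234,-0.026,-0.057,0.741,1
2016,region,benishangul,0.0102,-0.059,-0.002,-0.007,0.008,1
2016,region,snnpr,0.2074,0.005,0.005,-0.065,-0.147,1
2016,region,gambela,0.0029,-0.026,-0.0003,0.001,-0.0002,1
2016,region,harari,0.0025,-0.078,-0.0008,0.004,-0.002,1
2016,region,dire_dawa,0.0057,-0.048,-0.001,0.010,-0.005,1
2016,education,primary,0.4067,0.099,0.159,-0.005,-0.363,0
2016,education,secondary,0.1320,0.158,0.0818,0.214,8.69,1
2016,education,higher,0.0692,0.219,0.061,0.197,5.99,1
2016,marital,never_married,0.3268,0.023,0.029,0.180,2.60,1
2016,marital,widowed_divorced,0.0625,-0.001,-0.0002,0.007,-0.001,1
2016,religion,catholic,0.0072,-0.071,-0.002,0.002,-0.002,1
2016,religion,protestant,0.2285,-0.028,-0.026,0.028,-0.360,1
2016,religion,muslim,0.3130,-0.007,0.009,-0.201,0.908,0
2016,religion,traditional,0.0135,-0.060,-0.003,-0.026,0.0426,1
2016,employment,employed,0.6795,0.034,0.094,0.056,2.63,1
2016,wealth,poorer,0.1806,0.009,0.006,-0.356,-1.1,1
2016,wealth,middle,0.1915,0.007,0.005,-0.09,-0.238,1
2016,wealth,richer,0.2040,0.012,0.010,0.227,1.13,1
2016,wealth,richest,0.2601,0.055,0.057,0.768,21.59,1
2016,newspaper,yes,0.1963,0.023,0.018,0.286,2.61,1
2016,radio,yes,0.4107,-0.008,-0.013,0.374,-2.35,1
2016,tv,yes,0.3668,0.065,0.096,0.507,24.17,1
2016,household_head,female,0.1926,0.019,0.014,0.085,0.582,1
2016,tested,yes,0.4476,0.051,0.091,0.339,15.26,1
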