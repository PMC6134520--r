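province,tec,tc,ptec,sec,tfpc
Beijing,1.055,0.988,1.000,1.055,1.042
Tianjin,0.968,1.011,0.964,1.004,0.978
Hebei,1.039,0.965,0.962,1.081,1.003
Liaoning,1.038,0.955,1.031,1.007,0.992
Shanghai,1.000,1.014,1.000,1.000,1.014
Jiangsu,1.103,0.945,1.129,0.977,1.042
Zhejiang,1.029,1.011,1.000,1.029,1.041
Fujian,1.031,0.918,0.945,1.090,0.946
Shandong,1.015,0.950,0.800,1.269,0.964
Guangdong,1.033,0.975,0.993,1.040,1.007
Hainan,1.032,0.996,1.007,1.025,1.029
Shanxi,1.025,0.957,1.028,0.997,0.981
Jilin,0.977,0.981,0.979,0.998,0.958
Heilongjiang,1.180,0.904,1.093,1.079,1.066
Anhui,1.078,0.909,1.060,1.017,0.979
Jiangxi,1.099,0.878,0.989,1.112,0.966
Henan,1.070,0.935,0.940,1.138,1.000
Hubei,1.159,0.901,1.016,1.141,1.044
Hunan,1.171,0.877,1.072,1.093,1.027
Inner Mongolia,1.051,0.955,1.045,1.005,1.003
Chongqing,1.118,0.878,1.000,1.118,0.981
Guangxi,1.151,0.878,0.924,1.245,1.010
Sichuan,1.096,0.878,1.000,1.096,0.962
Guizhou,0.995,0.878,0.852,1.167,0.873
Yunnan,1.108,0.903,1.050,1.055,1.000
Tibet,1.000,0.987,1.000,1.000,0.987
Shaanxi,1.063,0.945,1.082,0.982,1.004
Gansu,1.051,0.960,1.049,1.002,1.009
Qinghai,1.000,0.907,1.000,1.000,0.907
Ningxia,1.000,0.985,1.000,1.000,0.985
Xinjiang,1.173,0.878,1.153,1.017,1.029
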