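temperature_c,k_per_min,k_sd,d_value_min,d_sd,half_life_min,half_life_sd
80,0.0016,0.0001,1428.57,25.67,429.96,13.45
90,0.0034,0.0002,666.66,17.59,200.65,11.26
100,0.0057,0.0010,400,19.35,120.39,16.78
110,0.0064,0.0009,357.14,8.89,107.49,11.27
120,0.0142,0.0028,161.29,7.66,48.54,2.24
130,0.0170,0.0026,135.13,3.82,40.67,2.87
140,0.0193,0.0025,119.04,4.61,35.83,2.98
150,0.0218,0.0027,105.26,2.39,31.68,1.97
160,0.0223,0.0013,103.09,2.19,31.02,2.67
170,0.0391,0.0018,58.82,1.12,17.70,1.43
180,0.0485,0.0029,47.39,1.14,14.26,1.82
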