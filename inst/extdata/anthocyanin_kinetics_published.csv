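temperature_c,k_per_min,k_sd,d_value_min,d_sd,half_life_min,half_life_sd
120,0.0228,0.00024,101.01,2.66,30.40,1.24
130,0.0499,0.00035,46.08,3.72,13.86,1.98
140,0.0739,0.00125,31.15,0.61,9.37,0.97
150,0.1437,0.0017,16.02,0.39,4.82,0.67
160,0.1695,0.0023,13.58,0.19,4.08,0.45
170,0.1929,0.0012,11.93,0.25,3.59,0.22
180,0.2268,0.0020,10.15,0.14,3.05,0.12
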