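formulation,zero_R2,zero_k0,first_R2,first_k1,higuchi_R2,higuchi_kH,kp_R2,kp_n,kp_kKP,hc_R2,hc_kHC
F1,0.77,7.862,0.956,0.114,0.979,19.855,0.994,0.591,16.614,0.929,0.032
F2,0.956,6.848,0.986,0.111,0.926,19.675,0.997,0.745,12.067,0.988,0.033
F3,0.931,7.055,0.977,0.118,0.942,20.405,0.995,0.700,13.717,0.975,0.034
F4,0.735,7.155,0.947,0.133,0.984,21.332,0.988,0.543,19.618,0.900,0.037
F5,0.938,7.057,0.985,0.118,0.94,20.382,0.998,0.710,13.426,0.984,0.034
F6,0.79,8.291,0.949,0.168,0.942,24.448,0.957,0.592,20.422,0.939,0.047
F7,0.909,7.310,0.976,0.127,0.955,21.253,0.996,0.668,15.258,0.971,0.036
F8,0.83,7.822,0.973,0.150,0.963,23.015,0.983,0.605,18.573,0.956,0.042
F9,0.85,7.404,0.98,0.135,0.957,21.723,0.983,0.623,17.065,0.96,0.038
F10,0.802,7.330,0.968,0.135,0.978,21.666,0.991,0.58,18.539,0.938,0.037
F11,0.738,8.063,0.869,0.157,0.958,22.927,0.957,0.547,21.785,0.85,0.043
F12,0.851,7.815,0.982,0.149,0.96,23.102,0.984,0.623,18.029,0.967,0.041
F13,0.849,7.850,0.978,0.151,0.944,23.534,0.982,0.611,18.579,0.961,0.042
F14,0.843,8.027,0.977,0.156,0.934,27.854,0.971,0.627,18.342,0.967,0.044
F15,0.359,9.091,0.952,0.262,0.934,27.854,0.948,0.435,31.511,0.896,0.075
F16,0.601,8.867,0.957,0.227,0.926,26.747,0.927,0.506,26.418,0.912,0.063
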