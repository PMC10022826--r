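formulation,weight_mg,weight_sd,friability_pct,friability_sd,hardness_kg_cm2,hardness_sd,thickness_mm,thickness_sd,diameter_mm,diameter_sd,content_pct,content_sd,lag_time_s,lag_time_sd,float_time_h,float_time_sd
F1,15.62,0.70,0.79,0.11,1.37,0.07,2.19,0.029,3.06,0.015,91.29,3.65,19,1.51,16,0.04
F2,15.4,1.03,0.61,0.07,1.27,0.02,2.15,0.024,3.07,0.02,96.7,2.05,35,1.52,22,0.07
F3,15.15,0.82,0.71,0.11,1.39,0.09,2.17,0.029,3.06,0.015,99.12,1.73,21,1.52,21.5,0.15
F4,14.35,0.93,0.87,0.13,1.47,0.9,2.12,0.026,3.05,0.012,95.84,1.92,45,1.52,18,0.12
F5,14.82,1.13,0.80,0.1,1.43,0.11,2.17,0.025,3.09,0.014,91.6,5.19,31,1.52,16,0.18
F6,14.82,0.82,0.86,0.11,1.57,0.08,2.09,0.028,3.08,0.017,91.29,3.65,65,1.52,17,0.07
F7,13.92,0.71,0.81,0.09,1.42,0.14,2.16,0.026,3.09,0.015,89.05,2.61,63,1.52,18,0.08
F8,14.65,1.27,0.69,0.05,1.47,0.02,2.11,0.023,3.1,0.015,88.92,3.93,23,1.52,18,0.11
F9,14.82,0.82,0.84,0.13,1.39,0.08,2.16,0.028,3.09,0.015,93.05,2.65,20,1.52,15.5,0.05
F10,14.85,0.54,0.73,0.12,1.45,0.08,2.17,0.029,3.10,0.016,97.64,1.82,23,1.52,17.5,0.15
F11,15.4,0.82,0.72,0.12,1.51,0.01,2.12,0.022,3.07,0.05,97.4,2.49,18,1.52,18,0.20
F12,14.98,1.01,0.82,0.08,1.43,0.08,2.17,0.027,3.09,0.012,92.46,5.4,26,1.52,18.5,0.12
F13,14.8,1.15,0.83,0.12,1.46,0.1,2.09,0.030,3.06,0.015,92.01,1.91,24,1.52,19,0.05
F14,14.45,1.05,0.79,0.11,1.38,0.08,2.15,0.028,3.1,0.015,92.01,1.82,34,1.52,18.4,0.081
F15,15.1,0.71,0.86,0.13,1.39,0.09,2.14,0.027,3.09,0.014,93.04,4.12,22,1.52,19,0.076
F16,15.6,1.01,0.76,0.12,1.44,0.09,2.14,0.020,3.1,0.016,90.6,3.2,24,1.52,17.5,0.15
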