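formulation,X1,X1_mg,X2,X2_mg,X3,X3_mg,mgst_pct,mgst_mg,drug_pct,drug_mg,net_mg
F1,44.5,6.67,0.0,0.00,14.6,2.18,1.0,0.15,40.0,6,15
F2,36.6,5.48,10.0,1.50,12.4,1.87,1.0,0.15,40.0,6,15
F3,45.0,6.75,4.6,0.69,9.4,1.41,1.0,0.15,40.0,6,15
F4,39.3,5.90,9.6,1.44,10.1,1.51,1.0,0.15,40.0,6,15
F5,39.2,5.88,4.9,0.73,14.9,2.23,1.0,0.15,40.0,6,15
F6,44.2,6.63,9.8,1.47,5.0,0.75,1.0,0.15,40.0,6,15
F7,44.2,6.63,9.8,1.47,5.0,0.75,1.0,0.15,40.0,6,15
F8,36.6,5.48,7.4,1.12,15.0,2.25,1.0,0.15,40.0,6,15
F9,44.5,6.67,0.0,0.00,14.6,2.18,1.0,0.15,40.0,6,15
F10,45.0,6.75,4.6,0.69,9.4,1.41,1.0,0.15,40.0,6,15
F11,34.0,5.10,10.0,1.50,15.0,2.25,1.0,0.15,40.0,6,15
F12,39.3,5.90,9.6,1.44,10.1,1.51,1.0,0.15,40.0,6,15
F13,40.8,6.12,6.4,0.96,11.8,1.77,1.0,0.15,40.0,6,15
F14,42.6,6.39,7.9,1.18,8.5,1.27,1.0,0.15,40.0,6,15
F15,43.0,6.45,3.2,0.48,12.8,1.92,1.0,0.15,40.0,6,15
F16,39.2,5.88,4.9,0.73,14.9,2.23,1.0,0.15,40.0,6,15
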