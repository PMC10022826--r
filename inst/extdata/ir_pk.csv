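metric,value
Cmax_ug_mL,4.866
Tmax_h,0.4812
AUC0_t_ug_mL_h,7.364
AUC0_inf_ug_mL_h,7.498
CL_L_h,7.342
Vd_L_kg,0.0381
K12_per_h,0.3013
K21_per_h,0.02116
dose_mg,60
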