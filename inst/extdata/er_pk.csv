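metric,value
Cmax_ug_mL,1.0958
Tmax_h,4.8
AUC0_t_ug_mL_h,14.448
AUC0_inf_ug_mL_h,15.459
dose_mg,120
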