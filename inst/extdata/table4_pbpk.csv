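parameter,value
logP,2.99
pKa,4.19
mw_g_mol,304.3
solubility_mg_mL,0.0268
diffusion_cm2_s,0.75e-5
particle_density_g_mL,1.62
peff_cm_s,5.31e-4
fup_pct,1
rbp,0.69
vc_L_kg,0.0381
k12_per_h,0.3013
k21_per_h,0.0211
cl_L_h_kg,0.10354
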