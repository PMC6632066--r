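material,d10_um,d50_um,d90_um,true_density_g_cm3,poisson,shear_modulus_pa,surface_energy_j_m2,e_pp,e_pw,mu_s_pp,mu_s_pw,mu_r_pp,mu_r_pw
amlodipine_besylate,2.74,10.50,28.70,1.36,0.25,1e7,0.00,0.20,0.20,0.50,0.50,0.50,0.50
smcc_90,29.71,106.48,223.88,1.61,0.25,1e7,0.00,0.30,0.50,0.40,0.40,0.20,0.30
pvp_k25,22.51,62.62,119.75,1.21,0.30,1e7,0.00,0.30,0.50,0.40,0.40,0.25,0.30
ccm_na,23.39,50.48,118.28,1.61,0.30,1e7,0.00,0.30,0.50,0.40,0.50,0.30,0.30
st_mg,1.09,5.52,24.99,1.11,0.30,1e7,0.02,0.30,0.30,0.50,0.50,0.45,0.40
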