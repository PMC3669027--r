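species_name,omega_min,omega_mode,omega_max,alpha50,alpha_ci_low,alpha_ci_high,alpha_trunc_low,alpha_trunc_high,fecundity_min,fecundity_max,eggcase_min,eggcase_mode,eggcase_max,survival_min,survival_max,tmax_observed,iape,extension_constant,growth_k,growth_t0,tl_max_cm,depth_mid_m,size_at_hatch_cm,size_at_maturity_cm,maturity_comment
Bathyraja lindbergi,31,32,46,17.7,16.2,19.2,18,21,16,52,0.65,0.98,0.99,0.77,0.95,32,,1.4,,,97,540,,,first maturity 18; 100% maturity 21
Bathyraja maculata,31,32,46,22.5,21.7,23.3,21,24,16,52,0.65,0.98,0.99,0.78,0.96,32,,1.4,,,120,564,,,first maturity 18; 100% maturity 30; CI-derived bounds 21 and 24 used
Bathyraja minispinosa,36,37,53,23.5,22.3,24.7,23,25,16,52,0.65,0.87,0.98,0.83,0.97,37,,1.4,,,90,635,,,first maturity 23; 100% maturity 25
Bathyraja taranetzi,13,14,20,9.2,8.7,9.7,8,10,16,52,0.65,0.81,0.98,0.60,0.91,14,,1.4,,,77,500,,,first maturity 8; 100% maturity 13; CI-derived upper bound 10 used
Bathyraja trachura,35,36,51,27.5,25.8,28.1,25,29,16,52,0.64,0.65,0.98,0.71,0.96,36,,1.4,,,94,1169,,,first maturity 22; 100% maturity 33; CI-derived bounds 25 and 29 used
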