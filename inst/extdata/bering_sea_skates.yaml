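species:
  - species_name: "Bathyraja lindbergi"
    omega_min:                 31
    omega_mode:                 32
    omega_max:                 46
    alpha50: 17.699999999999999
    alpha_ci_low: 16.199999999999999
    alpha_ci_high: 19.199999999999999
    alpha_trunc_low:                 18
    alpha_trunc_high:                 21
    fecundity_min:                 16
    fecundity_max:                 52
    eggcase_min: 0.65000000000000002
    eggcase_mode: 0.97999999999999998
    eggcase_max: 0.98999999999999999
    survival_min: 0.77000000000000002
    survival_max: 0.94999999999999996
    tmax_observed:                 32
    extension_constant: 1.3999999999999999
    tl_max_cm:                 97
    depth_mid_m:                540
    maturity_comment: "first maturity 18; 100% maturity 21"
  - species_name: "Bathyraja maculata"
    omega_min:                 31
    omega_mode:                 32
    omega_max:                 46
    alpha50:               22.5
    alpha_ci_low: 21.699999999999999
    alpha_ci_high: 23.300000000000001
    alpha_trunc_low:                 21
    alpha_trunc_high:                 24
    fecundity_min:                 16
    fecundity_max:                 52
    eggcase_min: 0.65000000000000002
    eggcase_mode: 0.97999999999999998
    eggcase_max: 0.98999999999999999
    survival_min: 0.78000000000000003
    survival_max: 0.95999999999999996
    tmax_observed:                 32
    extension_constant: 1.3999999999999999
    tl_max_cm:                120
    depth_mid_m:                564
    maturity_comment: "first maturity 18; 100% maturity 30; CI-derived bounds 21 and 24 used"
  - species_name: "Bathyraja minispinosa"
    omega_min:                 36
    omega_mode:                 37
    omega_max:                 53
    alpha50:               23.5
    alpha_ci_low: 22.300000000000001
    alpha_ci_high: 24.699999999999999
    alpha_trunc_low:                 23
    alpha_trunc_high:                 25
    fecundity_min:                 16
    fecundity_max:                 52
    eggcase_min: 0.65000000000000002
    eggcase_mode:               0.87
    eggcase_max: 0.97999999999999998
    survival_min: 0.82999999999999996
    survival_max: 0.96999999999999997
    tmax_observed:                 37
    extension_constant: 1.3999999999999999
    tl_max_cm:                 90
    depth_mid_m:                635
    maturity_comment: "first maturity 23; 100% maturity 25"
  - species_name: "Bathyraja taranetzi"
    omega_min:                 13
    omega_mode:                 14
    omega_max:                 20
    alpha50: 9.1999999999999993
    alpha_ci_low: 8.6999999999999993
    alpha_ci_high: 9.6999999999999993
    alpha_trunc_low:                  8
    alpha_trunc_high:                 10
    fecundity_min:                 16
    fecundity_max:                 52
    eggcase_min: 0.65000000000000002
    eggcase_mode: 0.81000000000000005
    eggcase_max: 0.97999999999999998
    survival_min: 0.59999999999999998
    survival_max: 0.91000000000000003
    tmax_observed:                 14
    extension_constant: 1.3999999999999999
    tl_max_cm:                 77
    depth_mid_m:                500
    maturity_comment: "first maturity 8; 100% maturity 13; CI-derived upper bound 10 used"
  - species_name: "Bathyraja trachura"
    omega_min:                 35
    omega_mode:                 36
    omega_max:                 51
    alpha50:               27.5
    alpha_ci_low: 25.800000000000001
    alpha_ci_high: 28.100000000000001
    alpha_trunc_low:                 25
    alpha_trunc_high:                 29
    fecundity_min:                 16
    fecundity_max:                 52
    eggcase_min: 0.64000000000000001
    eggcase_mode: 0.65000000000000002
    eggcase_max: 0.97999999999999998
    survival_min: 0.70999999999999996
    survival_max: 0.95999999999999996
    tmax_observed:                 36
    extension_constant: 1.3999999999999999
    tl_max_cm:                 94
    depth_mid_m:               1169
    maturity_comment: "first maturity 22; 100% maturity 33; CI-derived bounds 25 and 29 used"
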