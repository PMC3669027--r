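species_name,lambda_pub,alpha_omega_ratio,tl_max_cm,depth_mid_m,group
Rhinoraja interrupta,1.360,0.58,83,695,alaskan
Beringraja binoculata,1.334,0.19,244,402,alaskan
Bathyraja aleutica,1.252,0.53,154,809,alaskan
Leucoraja erinacea,1.234,0.50,57,192,other_high_latitude
Dipturus laevis,1.221,0.24,134,800,other_high_latitude
Raja rhina,1.202,0.35,204,320,alaskan
Amblyraja radiata,1.197,0.58,101,859,other_high_latitude
Leucoraja ocellata,1.139,0.43,111,186,other_high_latitude
Bathyraja taranetzi,1.116,0.66,77,500,alaskan
Bathyraja lindbergi,1.110,0.55,97,540,alaskan
Bathyraja minispinosa,1.096,0.64,90,635,alaskan
Bathyraja maculata,1.079,0.70,120,564,alaskan
Bathyraja trachura,1.048,0.75,94,1169,alaskan
Raja clavata,0.930,0.71,104,289,other_high_latitude
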