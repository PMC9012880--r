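wavelength_nm,eps_oxy_per_mM_cm,eps_deoxy_per_mM_cm,is_isosbestic
438,115.0,180.0,FALSE
450,62.0,62.0,TRUE
452,62.7,62.7,TRUE
500,5.3,5.3,TRUE
530,39.0,39.0,TRUE
545,51.0,51.0,TRUE
570,44.0,44.0,TRUE
584,33.0,33.0,TRUE
650,0.9,3.5,FALSE
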