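reaction,constant,value,provenance
pla2_hydrolysis,K_cat,0.012,synthetic
pla2_hydrolysis,K_m,50,synthetic
pla2_hydrolysis,KI,0.5,synthetic
lox5_oxygenation,K_cat,0.02,synthetic
lox5_oxygenation,K_m,8,synthetic
lox5_oxygenation,K_i,2,synthetic
phgpx_reduction_5,K_cat,0.05,synthetic
phgpx_reduction_5,K_m,5,synthetic
lta4_synthase,K_cat,0.03,synthetic
lta4_synthase,K_m,6,synthetic
lta4_hydrolase,K_cat,0.04,synthetic
lta4_hydrolase,K_m,3,synthetic
cyp4f3_omega_oxidation,K_cat,0.03,synthetic
cyp4f3_omega_oxidation,K_m,2,synthetic
lox15_oxygenation,K_cat,0.015,synthetic
lox15_oxygenation,K_m,10,synthetic
phgpx_reduction_15,K_cat,0.05,synthetic
phgpx_reduction_15,K_m,5,synthetic
lox12_oxygenation,K_cat,0.015,synthetic
lox12_oxygenation,K_m,10,synthetic
phgpx_reduction_12,K_cat,0.05,synthetic
phgpx_reduction_12,K_m,5,synthetic
cox2_oxygenation,K_cat,0.02,synthetic
cox2_oxygenation,K_m,5,synthetic
txa_synthase,K_cat,0.03,synthetic
txa_synthase,K_m,4,synthetic
pge_synthase,K_cat,0.03,synthetic
pge_synthase,K_m,4,synthetic
cox2_induction,k_max,1e-04,synthetic
cox2_induction,k_half,1,synthetic
cox2_inactivation,K,1e-04,synthetic
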