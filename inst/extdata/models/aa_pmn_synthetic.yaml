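species:
- id: PC
  initial: 250.0
  role: metabolite
- id: AA
  initial: 1.0
  role: metabolite
- id: 5-HPETE
  initial: 0.0
  role: metabolite
- id: 5-HETE
  initial: 0.0
  role: metabolite
- id: LTA4
  initial: 0.0
  role: metabolite
- id: LTB4
  initial: 0.0
  role: metabolite
- id: 20-OH-LTB4
  initial: 0.0
  role: metabolite
- id: 15-HPETE
  initial: 0.0
  role: metabolite
- id: 15-HETE
  initial: 0.0
  role: metabolite
- id: 12-HPETE
  initial: 0.0
  role: metabolite
- id: 12-HETE
  initial: 0.0
  role: metabolite
- id: PGH2
  initial: 0.0
  role: metabolite
- id: TXA2
  initial: 0.0
  role: metabolite
- id: PGE2
  initial: 0.0
  role: metabolite
- id: PLA2
  initial: 0.5
  role: enzyme_pool
- id: 5-LOX
  initial: 0.4
  role: enzyme_pool
- id: 15-LOX
  initial: 0.3
  role: enzyme_pool
- id: 12-LOX
  initial: 0.3
  role: enzyme_pool
- id: COX2
  initial: 0.5
  role: enzyme_pool
- id: TXAS
  initial: 0.3
  role: enzyme_pool
- id: PGES
  initial: 0.3
  role: enzyme_pool
- id: LTA4H
  initial: 0.6
  role: enzyme_pool
- id: CYP4F3
  initial: 0.2
  role: enzyme_pool
- id: PHGPx
  initial: 0.5
  role: enzyme_pool
reactions:
- id: pla2_hydrolysis
  law_kind: activation
  substrate: PC
  product: AA
  enzyme: PLA2
  modifiers:
    activator: LTB4
  constants:
    K_cat: 0.012
    K_m: 50.0
    KI: 0.5
- id: lox5_oxygenation
  law_kind: competitive_inhibition
  substrate: AA
  product: 5-HPETE
  enzyme: 5-LOX
  modifiers:
    inhibitor: 15-HETE
  constants:
    K_cat: 0.02
    K_m: 8.0
    K_i: 2.0
- id: phgpx_reduction_5
  law_kind: michaelis_menten
  substrate: 5-HPETE
  product: 5-HETE
  enzyme: PHGPx
  constants:
    K_cat: 0.05
    K_m: 5.0
- id: lta4_synthase
  law_kind: michaelis_menten
  substrate: 5-HPETE
  product: LTA4
  enzyme: 5-LOX
  constants:
    K_cat: 0.03
    K_m: 6.0
- id: lta4_hydrolase
  law_kind: michaelis_menten
  substrate: LTA4
  product: LTB4
  enzyme: LTA4H
  constants:
    K_cat: 0.04
    K_m: 3.0
- id: cyp4f3_omega_oxidation
  law_kind: michaelis_menten
  substrate: LTB4
  product: 20-OH-LTB4
  enzyme: CYP4F3
  constants:
    K_cat: 0.03
    K_m: 2.0
- id: lox15_oxygenation
  law_kind: michaelis_menten
  substrate: AA
  product: 15-HPETE
  enzyme: 15-LOX
  constants:
    K_cat: 0.015
    K_m: 10.0
- id: phgpx_reduction_15
  law_kind: michaelis_menten
  substrate: 15-HPETE
  product: 15-HETE
  enzyme: PHGPx
  constants:
    K_cat: 0.05
    K_m: 5.0
- id: lox12_oxygenation
  law_kind: michaelis_menten
  substrate: AA
  product: 12-HPETE
  enzyme: 12-LOX
  constants:
    K_cat: 0.015
    K_m: 10.0
- id: phgpx_reduction_12
  law_kind: michaelis_menten
  substrate: 12-HPETE
  product: 12-HETE
  enzyme: PHGPx
  constants:
    K_cat: 0.05
    K_m: 5.0
- id: cox2_oxygenation
  law_kind: michaelis_menten
  substrate: AA
  product: PGH2
  enzyme: COX2
  constants:
    K_cat: 0.02
    K_m: 5.0
- id: txa_synthase
  law_kind: michaelis_menten
  substrate: PGH2
  product: TXA2
  enzyme: TXAS
  constants:
    K_cat: 0.03
    K_m: 4.0
- id: pge_synthase
  law_kind: michaelis_menten
  substrate: PGH2
  product: PGE2
  enzyme: PGES
  constants:
    K_cat: 0.03
    K_m: 4.0
- id: cox2_induction
  law_kind: transcription_upregulation
  enzyme: COX2
  modifiers:
    transcription_signal: PGE2
  constants:
    k_max: 0.0001
    k_half: 1.0
- id: cox2_inactivation
  law_kind: irreversible_inactivation
  enzyme: COX2
  modifiers:
    inhibitor: 15-HPETE
  constants:
    K: 0.0001
targets:
- PLA2
- 5-LOX
- 15-LOX
- 12-LOX
- TXAS
- LTA4H
- CYP4F3
- PHGPx
readout: LTB4
horizon_seconds: 3600.0
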