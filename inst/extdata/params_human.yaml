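species: human
body_weight: 70.0
q_c: 910.0
q_p: 1400.0
diet_mg_per_day: 2.43
enterohepatic: yes
compartments:
  blood:
    mass: 5600.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 0.0
    k_a: 0.0
    k_d: 0.0
    k_absorb: 0.0
  liver:
    mass: 2100.0
    q_blood: 209.3
    k_in: 112.624361837083
    k_out: 37.729161215423
    b_max: 15.0
    k_a: 0.005
    k_d: 0.00079
    k_absorb: 0.0
  gut_lumen:
    mass: 1000.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 0.0
    k_a: 0.0
    k_d: 0.0
    k_absorb: 0.0
  gut_epithelium:
    mass: 300.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  lung_epithelium:
    mass: 700.0
    q_blood: 0.0
    k_in: 1.0
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  olfactory_epithelium:
    mass: 2.0
    q_blood: 0.0
    k_in: 0.005
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  respiratory_epithelium:
    mass: 15.0
    q_blood: 0.0
    k_in: 0.04
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  olfactory_bulb:
    mass: 0.2
    q_blood: 0.0143
    k_in: 0.001
    k_out: 0.0004
    b_max: 4.0
    k_a: 0.005
    k_d: 0.0007
    k_absorb: 0.0
  globus_pallidus:
    mass: 15.0
    q_blood: 1.07
    k_in: 0.0223
    k_out: 0.0053
    b_max: 20.0
    k_a: 0.00165
    k_d: 0.0018
    k_absorb: 0.0
  cerebellum:
    mass: 150.0
    q_blood: 10.7
    k_in: 0.75
    k_out: 0.3
    b_max: 4.0
    k_a: 0.005
    k_d: 0.0007
    k_absorb: 0.0
  pituitary:
    mass: 0.6
    q_blood: 0.043
    k_in: 0.006
    k_out: 0.0012
    b_max: 8.0
    k_a: 0.005
    k_d: 0.0011
    k_absorb: 0.0
  bone:
    mass: 8400.0
    q_blood: 36.4
    k_in: 2.66
    k_out: 2.0
    b_max: 4.0
    k_a: 0.005
    k_d: 0.00029
    k_absorb: 0.0
  kidney:
    mass: 310.0
    q_blood: 172.9
    k_in: 1.0
    k_out: 0.3
    b_max: 6.0
    k_a: 0.005
    k_d: 0.00058
    k_absorb: 0.0
  rest_of_body:
    mass: 51407.200000000004
    q_blood: 479.5727
    k_in: 10.0
    k_out: 10.0
    b_max: 2.0
    k_a: 0.005
    k_d: 0.00028
    k_absorb: 0.0
dep:
  f_nasal_olf: 0.02067692837
  f_nasal_resp: 0.10338464185
  f_pulm: 0.2067692837
  k_olf_transport: 0.005
  k_epith_absorb:
    lung: 0.5
    olfactory: 0.5
    respiratory: 0.5
gut:
  k_abs: 0.006
  k_fec: 0.05
  K_inh: 8000.0
  n_inh: 1.0
  k_slough: 0.1
  k_blood: 0.3
bile:
  k_bile_c: 0.316555622306
  i_max: 12.0
  c50_ind: 0.030183182195
  n_ind: 8.0
provenance:
  body_weight: 'assumed: reference adult (70 kg)'
  tissue_volumes: 'assumed: reference volume fractions (blood 8%, bone 12%, brain
    2%, liver 3%, lung 1% of BW)'
  blood_flows: 'assumed: reference flow fractions (bone 4%, brain 11%, liver 23%,
    nose 1% of q_c)'
  q_c: 'assumed: 13 L/h/kg'
  q_p: 'assumed: 20 L/h/kg'
  bile.k_bile_c: 'calibrated: basal globus pallidus anchor'
  bile.i_max: 'calibrated: occupational dose-response checkpoints'
  bile.c50_ind: 'calibrated: occupational dose-response checkpoints'
  bile.n_ind: 'calibrated: occupational dose-response checkpoints'
  dep.fractions: 'calibrated: 0.01 mg/m^3 dose-response checkpoint'
  gut.K_inh: 'calibrated: basal tissue concentrations'
  tissue.globus_pallidus.kinetics: 'calibrated: shared with monkey anchors, diffusional
    fluxes allometric in BW^0.75'
  diet_mg_per_day: 'reference: mean adult dietary intake 2.43 mg/day'
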