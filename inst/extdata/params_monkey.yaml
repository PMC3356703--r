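species: monkey
body_weight: 3.0
q_c: 60.0
q_p: 60.0
diet_mg_per_day: 13.3
enterohepatic: yes
compartments:
  blood:
    mass: 240.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 0.0
    k_a: 0.0
    k_d: 0.0
    k_absorb: 0.0
  liver:
    mass: 90.0
    q_blood: 13.8
    k_in: 5.66
    k_out: 0.3245
    b_max: 15.0
    k_a: 0.005
    k_d: 0.00079
    k_absorb: 0.0
  gut_lumen:
    mass: 100.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 0.0
    k_a: 0.0
    k_d: 0.0
    k_absorb: 0.0
  gut_epithelium:
    mass: 30.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  lung_epithelium:
    mass: 30.0
    q_blood: 0.0
    k_in: 0.094192735799
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  olfactory_epithelium:
    mass: 0.4
    q_blood: 0.0
    k_in: 0.000470963679
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  respiratory_epithelium:
    mass: 3.0
    q_blood: 0.0
    k_in: 0.003767709432
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  olfactory_bulb:
    mass: 0.1
    q_blood: 0.011
    k_in: 9.419273579878e-05
    k_out: 3.767709431951e-05
    b_max: 4.0
    k_a: 0.005
    k_d: 0.0007
    k_absorb: 0.0
  globus_pallidus:
    mass: 0.6
    q_blood: 0.066
    k_in: 0.002100498008
    k_out: 0.0004992215
    b_max: 20.0
    k_a: 0.00165
    k_d: 0.0018
    k_absorb: 0.0
  cerebellum:
    mass: 6.0
    q_blood: 0.66
    k_in: 0.070644551849
    k_out: 0.02825782074
    b_max: 4.0
    k_a: 0.005
    k_d: 0.0007
    k_absorb: 0.0
  pituitary:
    mass: 0.05
    q_blood: 0.0055
    k_in: 0.000565156415
    k_out: 0.000113031283
    b_max: 8.0
    k_a: 0.005
    k_d: 0.0011
    k_absorb: 0.0
  bone:
    mass: 360.0
    q_blood: 2.4
    k_in: 0.250552677225
    k_out: 0.188385471598
    b_max: 4.0
    k_a: 0.005
    k_d: 0.00029
    k_absorb: 0.0
  kidney:
    mass: 20.0
    q_blood: 11.4
    k_in: 0.094192735799
    k_out: 0.02825782074
    b_max: 6.0
    k_a: 0.005
    k_d: 0.00058
    k_absorb: 0.0
  rest_of_body:
    mass: 2119.85
    q_blood: 31.6575
    k_in: 0.941927357988
    k_out: 0.941927357988
    b_max: 2.0
    k_a: 0.005
    k_d: 0.00028
    k_absorb: 0.0
dep:
  f_nasal_olf: 0.034880779002
  f_nasal_resp: 0.139523116006
  f_pulm: 0.406942421684
  k_olf_transport: 0.005
  k_epith_absorb:
    lung: 0.5
    olfactory: 0.5
    respiratory: 0.5
gut:
  k_abs: 0.005
  k_fec: 0.05
  K_inh: 440.0
  n_inh: 1.0
  k_slough: 0.1
  k_blood: 0.3
bile:
  k_bile_c: 0.001760189075
  i_max: 8.0
  c50_ind: 0.0341
  n_ind: 6.0
provenance:
  body_weight: 'assumed: young adult rhesus (3 kg)'
  bile.k_bile_c: 'calibrated: basal pallidal anchor 0.48 ug/g'
  dep.fractions: 'calibrated: 65-exposure-day anchor 2.94 ug/g'
  gut.K_inh: 'calibrated: basal tissue concentrations at 133 ppm'
  tissue.globus_pallidus.kinetics: 'calibrated: 15/33/65-day trajectory and duration
    ratio'
  diet_mg_per_day: 'reference: 133 ppm diet, 100 g feed/day'
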