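species: rat
body_weight: 0.25
q_c: 5.0
q_p: 12.0
diet_mg_per_day: 2.25
enterohepatic: yes
compartments:
  blood:
    mass: 20.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 0.0
    k_a: 0.0
    k_d: 0.0
    k_absorb: 0.0
  liver:
    mass: 10.0
    q_blood: 1.15
    k_in: 0.876
    k_out: 0.077
    b_max: 15.0
    k_a: 0.005
    k_d: 0.00079
    k_absorb: 0.0
  gut_lumen:
    mass: 8.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 0.0
    k_a: 0.0
    k_d: 0.0
    k_absorb: 0.0
  gut_epithelium:
    mass: 3.0
    q_blood: 0.0
    k_in: 0.0
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  lung_epithelium:
    mass: 1.5
    q_blood: 0.0
    k_in: 0.014609369604
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  olfactory_epithelium:
    mass: 0.1
    q_blood: 0.0
    k_in: 7.304684802205e-05
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  respiratory_epithelium:
    mass: 0.3
    q_blood: 0.0
    k_in: 0.000584374784
    k_out: 0.0
    b_max: 1.0
    k_a: 0.005
    k_d: 0.0004
    k_absorb: 0.0
  olfactory_bulb:
    mass: 0.08
    q_blood: 0.024
    k_in: 1.460936960441e-05
    k_out: 5.843747841764e-06
    b_max: 4.0
    k_a: 0.0143
    k_d: 0.002
    k_absorb: 0.0
  striatum:
    mass: 0.1
    q_blood: 0.03
    k_in: 0.000325788942
    k_out: 7.742965890338e-05
    b_max: 20.0
    k_a: 0.0023
    k_d: 0.0025
    k_absorb: 0.0
  cerebellum:
    mass: 0.3
    q_blood: 0.09
    k_in: 0.010957027203
    k_out: 0.004382810881
    b_max: 4.0
    k_a: 0.0143
    k_d: 0.002
    k_absorb: 0.0
  pituitary:
    mass: 0.01
    q_blood: 0.003
    k_in: 8.765621762647e-05
    k_out: 1.753124352529e-05
    b_max: 8.0
    k_a: 0.005
    k_d: 0.0011
    k_absorb: 0.0
  bone:
    mass: 30.0
    q_blood: 0.2
    k_in: 0.038860923148
    k_out: 0.029218739209
    b_max: 4.0
    k_a: 0.005
    k_d: 0.00029
    k_absorb: 0.0
  kidney:
    mass: 2.0
    q_blood: 0.95
    k_in: 0.014609369604
    k_out: 0.004382810881
    b_max: 6.0
    k_a: 0.005
    k_d: 0.00058
    k_absorb: 0.0
  rest_of_body:
    mass: 174.61
    q_blood: 2.553
    k_in: 0.146093696044
    k_out: 0.146093696044
    b_max: 2.0
    k_a: 0.005
    k_d: 0.00028
    k_absorb: 0.0
dep:
  f_nasal_olf: 0.08
  f_nasal_resp: 0.25
  f_pulm: 0.07
  k_olf_transport: 0.005
  k_epith_absorb:
    lung: 0.5
    olfactory: 0.5
    respiratory: 0.5
gut:
  k_abs: 0.005
  k_fec: 0.05
  K_inh: 480.0
  n_inh: 1.0
  k_slough: 0.1
  k_blood: 0.3
bile:
  k_bile_c: 0.0034
  i_max: 8.0
  c50_ind: 0.0341
  n_ind: 6.0
provenance:
  body_weight: 'assumed: adult male rat (0.25 kg)'
  bile.k_bile_c: 'calibrated: basal striatal anchor'
  tissue.striatum.kinetics: 'calibrated: basal anchor; binding faster than primate
    (rapid post-exposure return)'
  diet_mg_per_day: 'reference: 125 ppm diet, 18 g feed/day'
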