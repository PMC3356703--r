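# Route-specific uptake and elimination: deposition, olfactory transport,
# dietary input, saturable gut absorption, sloughing, biliary induction,
# schedule gating and homeostasis properties.

test_that("inhaled deposition follows the lumped fractions", {
  dep <- deposition_params(0.02, 0.08, 0.1, 0.005, 0.5)
  expect_equal(unname(inhaled_deposition_rates(0, 1400, dep, TRUE)),
               c(0, 0, 0))
  fl <- inhaled_deposition_rates(0.2, 1400, dep, TRUE)
  expect_equal(fl[["lung_epithelium"]], 0.2 * 1400 * 0.1)  # 28 ug/h
  expect_equal(fl[["olfactory_epithelium"]], 0.2 * 1400 * 0.02)
  # schedule gating: no flux while exposure is off
  expect_equal(unname(inhaled_deposition_rates(0.2, 1400, dep, FALSE)),
               c(0, 0, 0))
  expect_error(deposition_params(0.5, 0.4, 0.2, 0.005, 0.5), "sum")
})

test_that("olfactory transport is first order in epithelial Mn", {
  expect_equal(olfactory_transport_flux(0, 0.01), 0)
  expect_equal(olfactory_transport_flux(5, 0.01), 0.05)
  expect_error(olfactory_transport_flux(-1, 0.01), ">= 0")
})

test_that("long-run olfactory split equals the two-exit closed form", {
  # all deposition on the olfactory epithelium; the fraction reaching the
  # bulb must converge to k_olf / (k_olf + k_epith_absorb)
  p <- make_two_compartment()
  p$dep <- deposition_params(1, 0, 0, k_olf_transport = 0.01,
                             k_epith_absorb = 0.5)
  p$model$q_p <- 10
  tc <- simulate_exposure(p, exposure_schedule(0.1, 24, 7, 40),
                          init = "zero", dt_out = 24)
  nm <- p$model$compartments$name
  last <- tc$states[nrow(tc$states), ]
  a_bulb <- last[[paste0("free.", "olfactory_bulb")]]
  deposited <- last[["cum_intake"]]
  in_epith <- last[["free.olfactory_epithelium"]] +
    last[["bound.olfactory_epithelium"]]
  expect_equal(a_bulb / (deposited - in_epith), 0.01 / 0.51,
               tolerance = 1e-3)
})

test_that("dietary input converts mg/day and ppm consistently", {
  s <- exposure_schedule(0, 0, 7, 10, diet_mg_per_day = 2.43)
  expect_equal(dietary_input_rate(s), 2430 / 24)  # 101.25 ug/h
  expect_equal(dietary_input_rate(
    exposure_schedule(0, 0, 7, 10, diet_mg_per_day = 0)), 0)
  s2 <- exposure_schedule(0, 0, 7, 10, diet_ppm = 133,
                          food_intake_g_per_day = 100)
  expect_equal(dietary_input_rate(s2), 133 * 100 / 1000 * 1000 / 24)
  expect_error(exposure_schedule(0, 0, 7, 10, diet_mg_per_day = 1,
                                 diet_ppm = 133,
                                 food_intake_g_per_day = 100),
               "not both")
})

test_that("gut absorption saturates with lumen load", {
  gut <- gut_params(k_abs = 0.4, k_fec = 0.1, K_inh = 50, n_inh = 1,
                    k_slough = 0.1, k_blood = 0.3)
  # trace limit: flux/a -> k_abs
  expect_equal(gut_absorption_flux(1e-8, gut) / 1e-8, 0.4,
               tolerance = 1e-9)
  # half inhibition at a = K_inh
  expect_equal(gut_absorption_flux(50, gut), 0.4 * 50 / 2)
  # effective absorbed fraction at a = 10 K (hand arithmetic):
  # uptake rate k_abs/11, fecal rate k_fec; fraction = (0.4/11)/(0.4/11+0.1)
  a <- 500
  fa <- gut_absorption_flux(a, gut)
  frac <- fa / (fa + gut$k_fec * a)
  expect_equal(frac, (0.4 / 11) / (0.4 / 11 + 0.1), tolerance = 1e-12)
  expect_error(gut_params(0.4, 0.1, K_inh = 0, n_inh = 1, k_slough = 0,
                          k_blood = 0.3), "K_inh")
})

test_that("enterocyte sloughing flux and steady-state split", {
  expect_equal(enterocyte_sloughing_flux(10, 0.02), 0.2)
  expect_equal(enterocyte_sloughing_flux(10, 0), 0)
  # long-run fecal share of absorbed Mn = k_slough/(k_slough + k_blood)
  p <- make_two_compartment()
  p$gut <- gut_params(k_abs = 1, k_fec = 1e-7, K_inh = 1e9, n_inh = 1,
                      k_slough = 0.1, k_blood = 0.3)
  p$diet_mg_per_day <- 0.24  # 10 ug/h
  tc <- simulate_exposure(p, exposure_schedule(0, 0, 7, 60),
                          init = "zero", dt_out = 24)
  last <- tc$states[nrow(tc$states), ]
  in_gut <- last[["free.gut_lumen"]] + last[["free.gut_epithelium"]] +
    last[["bound.gut_epithelium"]]
  expect_equal(last[["cum_fecal"]] / (last[["cum_intake"]] - in_gut),
               0.1 / 0.4, tolerance = 2e-3)
})

test_that("biliary excretion is induced by liver free Mn", {
  bil <- biliary_params(k_bile_c = 0.002, i_max = 2, c50_ind = 0.1,
                        n_ind = 1)
  expect_equal(biliary_excretion_flux(0, bil), 0)
  # no induction: strictly linear clearance
  bil0 <- biliary_params(k_bile_c = 0.002, i_max = 0)
  expect_equal(biliary_excretion_flux(0.3, bil0), 1000 * 0.002 * 0.3)
  # half-maximal induction at c50: f_ind = 2 for i_max = 2
  expect_equal(biliary_induction_factor(0.1, bil), 2)
  expect_equal(biliary_excretion_flux(0.1, bil),
               2 * 1000 * 0.002 * 0.1)
  # induction factor bounded in [1, 1 + i_max]
  cf <- 10^seq(-4, 2, length.out = 25)
  fi <- vapply(cf, biliary_induction_factor, numeric(1), bil = bil)
  expect_true(all(fi >= 1 & fi <= 3))
  expect_true(all(diff(fi) >= 0))
})

test_that("weekly inhaled intake matches the schedule exactly", {
  p <- cached_species("monkey")
  sch <- exposure_schedule(0.5, 6, 5, 7, diet_mg_per_day = 0)
  tc <- simulate_exposure(p, sch, init = "zero", dt_out = 1)
  fdep <- p$dep$f_nasal_olf + p$dep$f_nasal_resp + p$dep$f_pulm
  expected <- 0.5 * p$model$q_p * fdep * 6 * 5
  got <- tc$states[nrow(tc$states), "cum_intake"]
  expect_equal(unname(got), expected, tolerance = 1e-9)
})

test_that("diet and inhalation add linearly at trace levels", {
  p <- cached_species("human")
  run <- function(diet, air) {
    sch <- exposure_schedule(air, 24, 7, 60, diet_mg_per_day = diet)
    tc <- simulate_exposure(p, sch, init = "zero", dt_out = 24)
    tissue_concentration(tc)[length(tc$times)]
  }
  c_diet <- run(1e-3, 0)
  c_inh <- run(0, 1e-6)
  c_both <- run(1e-3, 1e-6)
  expect_equal(c_both, c_diet + c_inh, tolerance = 0.01)
})

test_that("steady-state body burden rises sublinearly with diet", {
  p <- cached_species("human")
  diets <- c(1, 3.2, 10) * 101.25  # 10-fold range in ug/h
  tot <- vapply(diets, function(d)
    sum(steady_state_solve(p, diet_ug_h = d)$state), numeric(1))
  expect_true(all(diff(tot) > 0))          # strictly increasing
  expect_lt(tot[3] / tot[1], 10)           # sublinear over 10x
  # absorbed fraction falls with diet
  frac <- vapply(diets, function(d) {
    ss <- steady_state_solve(p, diet_ug_h = d)
    a <- ss$state[["free.gut_lumen"]]
    gut_absorption_flux(a, p$gut) / (d + biliary_excretion_flux(
      ss$state[["free.liver"]] / 2100, p$bile))
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})
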