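# Core compartmental kinetics: right-hand side laws, solver accuracy,
# conservation and capacity invariants.

test_that("right-hand side vanishes for an empty body with no exposure", {
  toy <- make_two_compartment()
  d <- evaluate_rhs(0, two_compartment_state(0, 0, 0), toy)
  expect_equal(unname(d), rep(0, 31))
})

test_that("a saturated binding site at zero free Mn only dissociates", {
  toy <- make_two_compartment()
  y <- two_compartment_state(a_blood = 0, a_free = 0, a_bound = 100)
  d <- evaluate_rhs(0, y, toy)
  expect_equal(d[["bound.globus_pallidus"]], -0.001 * 100)
  expect_equal(d[["free.globus_pallidus"]], +0.001 * 100)
})

test_that("two-compartment derivatives match hand-evaluated arithmetic", {
  # blood 2 ug in 1000 g (2 ug/L); tissue free 5 ug in 100 g; bound 20 of
  # 100 ug capacity.  Hand oracle, computed before implementation:
  #   influx  = k_in  * C_blood = 1 L/h * 2 ug/L            =  2 ug/h
  #   efflux  = k_out * C_free  = 0.5 L/h * 50 ug/L         = 25 ug/h
  #   binding = 0.01 * 0.05 * (100 - 20) - 0.001 * 20       = 0.02 ug/h
  toy <- make_two_compartment()
  d <- evaluate_rhs(0, two_compartment_state(2, 5, 20), toy)
  expect_equal(d[["free.globus_pallidus"]], 2 - 25 - 0.02)
  expect_equal(d[["bound.globus_pallidus"]], 0.02)
  expect_equal(d[["free.blood"]], 25 - 2)
  expect_equal(sum(d), 0)  # closed system
})

test_that("negative state components are rejected", {
  toy <- make_two_compartment()
  y <- two_compartment_state()
  y[["free.blood"]] <- -1
  expect_error(evaluate_rhs(0, y, toy), "negative")
})

test_that("compiled and reference right-hand sides agree", {
  for (sp in c("monkey", "human")) {
    p <- cached_species(sp)
    parms <- mnpbpk:::pack_parms(p, air = 0.3, exposure_on = 1,
                                 diet_ug_h = 200)
    set.seed(7)
    for (i in 1:5) {
      y <- abs(rnorm(31, 0, 1)) * c(rep(5, 14), rep(2, 14), 0, 0, 0)
      y[15:28] <- pmin(y[15:28],
                       p$model$compartments$b_max *
                         p$model$compartments$mass)
      dR <- evaluate_rhs(0, setNames(y, names(two_compartment_state())),
                         p, air = 0.3, exposure_on = TRUE,
                         diet_ug_h = 200)
      dC <- mnpbpk:::rhs_compiled(y, parms)
      expect_equal(unname(dR), dC, tolerance = 1e-12)
    }
  }
})

test_that("solver reproduces the infusion-elimination closed form", {
  toy <- make_toy_fixture(infusion_ug_h = 10, k_loss = 0.1)
  tc <- simulate_exposure(toy$params, toy$schedule, t_end_days = 10,
                          init = "zero")
  amount <- tissue_concentration(tc, "gut_lumen") *
    toy$params$model$compartments$mass[
      toy$params$model$compartments$name == "gut_lumen"]
  exact <- toy$analytic(tc$times)
  expect_lt(max(abs(amount[-1] - exact[-1]) / exact[-1]), 1e-6)
  # closed-form values at the fixture's own checkpoints
  expect_equal(toy$analytic(0), 0)
  expect_equal(toy$analytic(10), 100 * (1 - exp(-1)))
  expect_equal(toy$analytic(1e6), 100, tolerance = 1e-12)
})

test_that("adaptive solver matches fixed-step RK4 on the toy system", {
  toy <- make_two_compartment()
  y0 <- two_compartment_state(2, 5, 20)
  tc <- simulate_exposure(toy, exposure_schedule(0, 0, 7, 1),
                          t_end_days = 10 / 24, init = unname(y0),
                          dt_out = 10)
  yrk <- rk4_integrate(toy, y0, t_end = 10, dt = 0.001)
  yad <- tc$states[nrow(tc$states), ]
  nz <- abs(yrk) > 1e-12
  expect_lt(max(abs(yad[nz] - yrk[nz]) / abs(yrk[nz])), 1e-5)
})

test_that("the diet-only steady state is invariant under simulation", {
  p <- cached_species("monkey")
  tc <- simulate_exposure(p, exposure_schedule(0, 0, 7, 30),
                          init = "steady_state", dt_out = 24)
  conc0 <- tissue_concentration(tc)[1]
  drift <- abs(tissue_concentration(tc) - conc0) / conc0
  expect_lt(max(drift), 1e-4)
})

test_that("mass balance closes to 1e-6 and detects corruption", {
  p <- cached_species("rat")
  tc <- simulate_exposure(p, exposure_schedule(0.5, 6, 5, 14))
  expect_lt(check_mass_balance(tc), 1e-6)
  bad <- tc
  bad$states[100, "free.liver"] <- bad$states[100, "free.liver"] + 50
  expect_gt(check_mass_balance(bad), 1e-4)
})

test_that("closed system conserves total Mn exactly", {
  toy <- make_two_compartment()
  tc <- simulate_exposure(toy, exposure_schedule(0, 0, 7, 2),
                          init = unname(two_compartment_state(2, 5, 20)),
                          dt_out = 1)
  total <- rowSums(tc$states[, 1:28])
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-9)
  expect_lt(check_mass_balance(tc), 1e-9)
})

test_that("bound Mn never exceeds the binding capacity", {
  p <- cached_species("monkey")
  tc <- simulate_exposure(p, canned_schedules()$dorman_65day)
  btot <- p$model$compartments$b_max * p$model$compartments$mass
  for (i in seq_len(14)) {
    if (btot[i] > 0)
      expect_lt(max(tc$states[, 14 + i]), btot[i] * (1 + 1e-9))
  }
})

test_that("brain Mn returns to baseline after exposure ends", {
  p <- cached_species("rat")
  basal <- steady_state_solve(p)$conc[["striatum"]]
  tc <- simulate_exposure(p, exposure_schedule(0.5, 6, 5, 90),
                          t_end_days = 150)
  conc <- tissue_concentration(tc, "striatum")
  expect_gt(max(conc), basal * 1.2)  # exposure raised the tissue
  expect_lt(abs(conc[length(conc)] - basal) / basal, 0.05)
  # free striatal Mn decays monotonically through washout
  free <- tissue_concentration(tc, "striatum", "free")
  post <- free[tc$times > 90 * 24]
  expect_true(all(diff(post) <= 1e-12))
})

test_that("piecewise integration honours exposure transitions", {
  segs <- expand_schedule(exposure_schedule(0.2, 8, 5, 14))
  expect_true(all(segs$t1 > segs$t0))
  expect_equal(segs$t0[1], 0)
  expect_equal(max(segs$t1), 14 * 24)
  # merged off-phases: weekend gap appears as one 64-h segment
  off <- segs[!segs$exposure_on, ]
  expect_true(any(abs(off$t1 - off$t0 - 64) < 1e-9))
  # total on-time equals 8 h x 10 exposure days
  expect_equal(sum(segs$t1[segs$exposure_on] - segs$t0[segs$exposure_on]),
               8 * 10)
})
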