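# Scenario modifiers, dose metrics and CSAF computation.

test_that("scenario validation rejects bad modifiers", {
  expect_error(scenario("x", c(0.5)), "named")
  expect_error(scenario("x", c("bile.k_bile_c" = -1)), "> 0")
  expect_error(scenario("x", c("bile.nonsense" = 0.5)), "unknown")
  expect_silent(scenario("ok", c("q_p" = 0.75)))
})

test_that("apply_scenario multiplies parameters and rebalances flow", {
  p <- cached_species("human")
  scn <- scenario_hepatic_impaired()
  q <- apply_scenario(p, scn)
  cm0 <- p$model$compartments
  cm1 <- q$model$compartments
  il <- match("liver", cm0$name); ir <- match("rest_of_body", cm0$name)
  expect_equal(cm1$q_blood[il], cm0$q_blood[il] * 0.5)
  expect_equal(q$bile$k_bile_c, p$bile$k_bile_c * 0.5)
  # freed liver flow returns to the rest-of-body residual
  expect_equal(cm1$q_blood[ir],
               cm0$q_blood[ir] + cm0$q_blood[il] * 0.5)
  # original untouched; empty scenario is the identity
  expect_equal(p$bile$k_bile_c, cached_species("human")$bile$k_bile_c)
  expect_equal(apply_scenario(p, scenario("id"))$model$compartments, cm0)
  # aged scenario reduces minute volume only
  aged <- apply_scenario(p, scenario_aged())
  expect_equal(aged$model$q_p, p$model$q_p * 0.75)
  expect_equal(aged$model$q_c, p$model$q_c)
})

test_that("infeasible flow modifiers are rejected", {
  p <- cached_species("human")
  expect_error(apply_scenario(p, scenario("bad",
                                          c("tissue.liver.q_blood" = 5))),
               "negative|exceed")
})

test_that("dose metrics match closed forms on constructed courses", {
  toy <- make_two_compartment()
  mk_tc <- function(times, conc, on) {
    states <- matrix(0, length(times), 31,
                     dimnames = list(NULL, names(two_compartment_state())))
    states[, "free.globus_pallidus"] <- conc * 100  # mass 100 g
    structure(list(times = times, states = states, exposure_on = on,
                   params = toy, schedule = exposure_schedule(0, 0, 7, 1),
                   diet_ug_h = 0, settings = list()),
              class = "mn_timecourse")
  }
  # constant 0.5 ug/g over 24 h -> average daily AUC 12 ug*h/g/day
  tc <- mk_tc(seq(0, 24, by = 1), rep(0.5, 25), rep(FALSE, 25))
  expect_equal(average_daily_auc(tc, "globus_pallidus"), 12)
  expect_equal(end_of_exposure_concentration(tc, "globus_pallidus"), 0.5)
  # linear ramp 0 -> 1 over one day -> 12 (trapezoid closed form)
  tc2 <- mk_tc(seq(0, 24, by = 1), seq(0, 1, length.out = 25),
               rep(FALSE, 25))
  expect_equal(average_daily_auc(tc2, "globus_pallidus"), 12)
  expect_error(average_daily_auc(tc2, "globus_pallidus", window = 2),
               "exceeds")
  # end of exposure = last on-phase value, not the global end
  on <- c(rep(TRUE, 10), rep(FALSE, 15))
  tc3 <- mk_tc(seq(0, 24, by = 1), seq(1, 0.5, length.out = 25), on)
  expect_equal(end_of_exposure_concentration(tc3, "globus_pallidus"),
               seq(1, 0.5, length.out = 25)[10])
  expect_equal(c_max(tc3, "globus_pallidus"), 1)
})

test_that("end-of-exposure sampling agrees with a dense grid", {
  p <- cached_species("rat")
  sch <- exposure_schedule(0.5, 6, 5, 10)
  coarse <- simulate_exposure(p, sch, dt_out = 2)
  dense <- simulate_exposure(p, sch, dt_out = 0.25)
  expect_equal(end_of_exposure_concentration(coarse),
               end_of_exposure_concentration(dense), tolerance = 1e-6)
})

test_that("percent change and CSAF arithmetic", {
  expect_equal(percent_change_from_basal(0.5, 0.5), 0)
  expect_equal(percent_change_from_basal(0.65, 0.5), 30)
  expect_equal(percent_change_from_basal(0.5045, 0.5), 0.9)
  expect_error(percent_change_from_basal(1, 0), "> 0")
  expect_equal(compute_csaf(0.85, 0.68), 1.25)
  expect_equal(compute_csaf(1, 1), 1)
  expect_equal(compute_csaf(7.9, 9.3), 7.9 / 9.3)  # 0.8495, infant/adult
  # scale invariance
  set.seed(1)
  for (k in runif(5, 0.1, 10))
    expect_equal(compute_csaf(0.85 * k, 0.68 * k), 1.25)
})

test_that("hepatic impairment raises pallidal Mn at every air level", {
  p <- cached_species("human")
  imp <- apply_scenario(p, scenario_hepatic_impaired())
  # at zero exposure (diet only)
  expect_gt(steady_state_solve(imp)$conc[["globus_pallidus"]],
            steady_state_solve(p)$conc[["globus_pallidus"]])
  # at the RfC and an intermediate level (short runs suffice)
  for (air in c(5e-5, 0.02)) {
    sch <- exposure_schedule(air, 8, 5, 30)
    expect_gt(end_of_exposure_concentration(simulate_exposure(imp, sch)),
              end_of_exposure_concentration(simulate_exposure(p, sch)))
  }
})

test_that("aged scenario lowers brain Mn at multiple exposures", {
  r <- cached_species("rat")
  aged <- apply_scenario(r, scenario_aged())
  for (air in c(0.1, 0.5)) {
    sch <- exposure_schedule(air, 6, 7, 30)
    csaf <- compute_csaf(
      end_of_exposure_concentration(simulate_exposure(aged, sch)),
      end_of_exposure_concentration(simulate_exposure(r, sch)))
    expect_lt(csaf, 1)
  }
})
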