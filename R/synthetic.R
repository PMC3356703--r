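# Synthetic data: closed-form fixtures and noisy tissue observations with
# known ground truth, so every downstream test can compute exact error.

#' One-compartment infusion-elimination fixture
#'
#' A constant infusion `R` (ug/h) into a pool with first-order loss `k`
#' (h^-1) has the closed-form solution `A(t) = (R/k) * (1 - exp(-k t))`
#' from `A(0) = 0`.  The fixture realizes this system inside the full
#' model: the infusion is the dietary input into the gut lumen and the
#' loss is the lumen fecal transit, with every other rate set to zero, so
#' the package solver can be checked against the analytic solution
#' end-to-end.
#'
#' @param infusion_ug_h infusion rate `R` (ug/h).
#' @param k_loss first-order loss rate `k` (h^-1).
#' @return list with `params` (a degenerate `mn_species`), `schedule`,
#'   `compartment` (`"gut_lumen"`), and `analytic(t)` returning the exact
#'   amount (ug).
#' @export
make_toy_fixture <- function(infusion_ug_h = 10, k_loss = 0.1) {
  stopifnot(infusion_ug_h >= 0, k_loss > 0)
  cm <- do.call(rbind, lapply(mn_compartments("globus_pallidus"),
                              function(nm) tissue_params(nm, mass = 1)))
  cm$mass[cm$name == "rest_of_body"] <- 100
  model <- model_spec("toy", cm, q_c = 1, q_p = 1)
  params <- species_params(
    species = "toy", body_weight = 0.1, model = model,
    dep = deposition_params(0, 0, 0, 0, 0),
    gut = gut_params(k_abs = 1e-12, k_fec = k_loss, K_inh = 1e12,
                     n_inh = 1, k_slough = 0, k_blood = 0),
    bile = biliary_params(0),
    diet_mg_per_day = infusion_ug_h * 24 / 1000)
  list(params = params,
       schedule = exposure_schedule(0, 0, 7, 30,
                                    diet_mg_per_day = params$diet_mg_per_day),
       compartment = "gut_lumen",
       analytic = function(t) infusion_ug_h / k_loss *
         (1 - exp(-k_loss * t)))
}

#' Generate noisy synthetic tissue observations
#'
#' Simulates the model, samples the requested tissues at the requested
#' times, and multiplies by lognormal noise `exp(eps)` with
#' `eps ~ Normal(0, sigma)`, `sigma = sqrt(log(1 + cv^2))`, so the
#' observation CV equals `noise_cv` and observations stay positive.  The
#' noiseless truth is retained in the output; note
#' `E[observed | true] = true * exp(sigma^2 / 2)`.
#'
#' @param params an `mn_species` parameter set (ground truth).
#' @param schedule an [exposure_schedule()].
#' @param tissues compartment names to observe.
#' @param times_h sampling times (h), within the simulated horizon.
#' @param noise_cv observation coefficient of variation (>= 0).
#' @param seed integer seed; tables are reproducible per seed.
#' @return `data.frame` with columns `time_h`, `tissue`, `observed`,
#'   `true`, `noise_cv`, `seed`.
#' @export
generate_synthetic_observations <- function(params, schedule, tissues,
                                            times_h, noise_cv, seed) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  t_end <- schedule$duration_days * 24
  if (any(times_h < 0 | times_h > t_end))
    stop("times must lie within the simulated horizon")
  tc <- simulate_exposure(params, schedule)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  sigma <- sqrt(log(1 + noise_cv^2))
  out <- lapply(tissues, function(ts) {
    conc <- tissue_concentration(tc, ts)
    tr <- stats::approx(tc$times, conc, xout = times_h)$y
    data.frame(time_h = times_h, tissue = ts,
               observed = tr * exp(stats::rnorm(length(times_h), 0,
                                                sigma)),
               true = tr, noise_cv = noise_cv, seed = seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
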