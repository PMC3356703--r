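# Monte Carlo population variability: truncated-normal parameter sampling
# and population summaries of globus pallidus concentration across air
# levels.

#' Sample from a doubly truncated normal distribution
#'
#' Rejection sampling of `Normal(mean, sd)` restricted to
#' `[mean - k*sd, mean + k*sd]` intersected with optional hard bounds.
#'
#' @param n number of samples.
#' @param mean,sd distribution mean and standard deviation (`sd = 0`
#'   returns `mean` exactly).
#' @param truncation_k truncation half-width in standard deviations
#'   (default 2).
#' @param hard_bounds optional `c(lo, hi)` absolute bounds.
#' @param seed optional integer seed (local to this call).
#' @return numeric vector of `n` samples.
#' @export
sample_truncated_normal <- function(n, mean, sd, truncation_k = 2,
                                    hard_bounds = NULL, seed = NULL) {
  stopifnot(n >= 1, sd >= 0)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  lo <- mean - truncation_k * sd
  hi <- mean + truncation_k * sd
  if (!is.null(hard_bounds)) {
    lo <- max(lo, hard_bounds[1])
    hi <- min(hi, hard_bounds[2])
  }
  if (lo > hi) stop("empty feasible interval [", lo, ", ", hi, "]")
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Mean of a doubly truncated normal distribution
#'
#' Closed-form moment used as the independent check of the sampler.
#'
#' @param mean,sd parent distribution parameters.
#' @param lo,hi truncation bounds.
#' @return expected value of the truncated distribution.
#' @export
truncated_normal_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Default population parameter distributions
#'
#' The adult human population variability specification: dietary Mn intake
#' mean 2.43, SD 1.8 mg/day with hard range 0.07-6.2 mg/day; body weight,
#' tissue volumes and tissue blood flows with coefficient of variation
#' 0.30; cardiac output and pulmonary ventilation with CV 0.50.  All
#' distributions are truncated at +/- 2 SD and sampled independently (no
#' parameter correlations).
#'
#' @return a list of per-parameter entries `(mean, sd or cv, truncation_k,
#'   hard_bounds)`, class `mn_distributions`.
#' @export
default_parameter_distributions <- function() {
  structure(list(
    diet = list(mean = 2.43, sd = 1.8, truncation_k = 2,
                hard_bounds = c(0.07, 6.2)),
    body_weight = list(cv = 0.30, truncation_k = 2),
    tissue_volume = list(cv = 0.30, truncation_k = 2),
    blood_flow = list(cv = 0.30, truncation_k = 2),
    cardiac_output = list(cv = 0.50, truncation_k = 2),
    ventilation = list(cv = 0.50, truncation_k = 2)
  ), class = "mn_distributions")
}

#' Sample a population of parameter sets
#'
#' Draws `n` independent subjects around a base (human) parameter set.
#' Body weight, per-tissue volume multipliers and per-tissue blood-flow
#' multipliers are sampled with CV 0.30; cardiac output and ventilation
#' multipliers with CV 0.50; dietary intake from its truncated
#' distribution.  Derived quantities are recomputed per subject: tissue
#' masses scale with body weight, flows with cardiac output, binding
#' capacities with tissue mass, and clearances/diffusional fluxes
#' allometrically with body weight.  Rest-of-body mass and flow take the
#' residuals; infeasible draws (negative residuals) are redrawn.
#'
#' @param dists an `mn_distributions` list.
#' @param base base `mn_species` set (the adult human).
#' @param n number of subjects.
#' @param seed integer seed; sampling is reproducible per seed.
#' @return list of `n` `mn_species` sets, each with a `diet_mg_per_day`
#'   of its own.
#' @export
sample_population <- function(dists, base, n, seed) {
  stopifnot(inherits(dists, "mn_distributions"),
            inherits(base, "mn_species"), n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  mult <- function(entry, m = 1) {
    if (is.null(entry$cv) || entry$cv == 0) return(m)
    k <- if (is.null(entry$truncation_k)) 2 else entry$truncation_k
    sample_truncated_normal(1, m, entry$cv * m, truncation_k = k)
  }
  subjects <- vector("list", n)
  cm0 <- base$model$compartments
  irest <- match("rest_of_body", cm0$name)
  bw0 <- base$body_weight
  for (s in seq_len(n)) {
    ok <- FALSE
    tries <- 0L
    while (!ok) {
      tries <- tries + 1L
      if (tries > 1e6) stop("no feasible subject after 1e6 redraws")
      bw <- mult(dists$body_weight, bw0)
      qc <- base$model$q_c / bw0 * bw * mult(dists$cardiac_output)
      qp <- base$model$q_p / bw0 * bw * mult(dists$ventilation)
      diet <- sample_truncated_normal(
        1, dists$diet$mean, dists$diet$sd, dists$diet$truncation_k,
        dists$diet$hard_bounds)
      cm <- cm0
      fbw <- bw / bw0
      fall <- fbw^0.75
      for (i in seq_len(nrow(cm))[-irest]) {
        cm$mass[i] <- cm0$mass[i] * fbw * mult(dists$tissue_volume)
        cm$q_blood[i] <- cm0$q_blood[i] / base$model$q_c * qc *
          mult(dists$blood_flow)
      }
      cm$k_in <- cm0$k_in * fall
      cm$k_out <- cm0$k_out * fall
      cm$mass[irest] <- bw * 1000 - sum(cm$mass[-irest])
      cm$q_blood[irest] <- NA_real_
      if (cm$mass[irest] <= 0 || sum(cm$q_blood[-irest]) >= qc) next
      sp <- base
      sp$body_weight <- bw
      sp$diet_mg_per_day <- diet
      sp$bile$k_bile_c <- base$bile$k_bile_c * fall
      sp$model <- model_spec(base$model$species, cm, q_c = qc, q_p = qp,
                             oral = base$model$oral,
                             inhalation = base$model$inhalation)
      subjects[[s]] <- sp
      ok <- TRUE
    }
  }
  subjects
}

#' Empirical distribution summary
#'
#' @param values nonempty numeric vector.
#' @return named vector `min`, `p5`, `median`, `p95`, `max` (empirical
#'   quantiles with linear interpolation).
#' @export
summarize_distribution <- function(values) {
  if (!length(values)) stop("empty input")
  q <- stats::quantile(values, c(0, 0.05, 0.5, 0.95, 1), names = FALSE,
                       type = 7)
  c(min = q[1], p5 = q[2], median = q[3], p95 = q[4], max = q[5])
}

#' Run the population Monte Carlo simulation
#'
#' Simulates each sampled subject for `duration_days` of continuous
#' (24 h/d, 7 d/wk) inhalation at each air level, starting from the
#' subject's diet-only steady state, and summarizes the end-of-exposure
#' brain target concentration across subjects.
#'
#' @param dists an `mn_distributions` list.
#' @param base base `mn_species` set.
#' @param air_levels air concentrations (mg/m^3); 0 gives the diet-only
#'   distribution.
#' @param n number of subjects.
#' @param seed integer seed.
#' @param duration_days exposure duration (default 365).
#' @param rtol,atol solver tolerances (defaults loosened for population
#'   throughput; see the methods vignette).
#' @return an object of class `mn_population`: list with `values`
#'   (n x length(air_levels) matrix of pallidal concentrations),
#'   `summary` (data.frame of quantiles per air level), `n`, `seed`,
#'   `air_levels` and `failures`.
#' @export
run_population <- function(dists, base, air_levels, n, seed,
                           duration_days = 365, rtol = 1e-6, atol = 1e-8) {
  stopifnot(n >= 1, all(air_levels >= 0))
  subjects <- sample_population(dists, base, n, seed)
  values <- matrix(NA_real_, n, length(air_levels))
  failures <- data.frame(subject = integer(), air = numeric(),
                         message = character())
  for (s in seq_len(n)) {
    sp <- subjects[[s]]
    ss <- steady_state_solve(sp, rtol = rtol, atol = atol)
    y0 <- numeric(N_STATE)
    y0[seq_len(2 * N_CMT)] <- ss$state
    for (a in seq_along(air_levels)) {
      res <- tryCatch({
        if (air_levels[a] == 0) {
          itar <- match(sp$model$target, sp$model$compartments$name)
          ss$conc[[itar]]
        } else {
          sch <- exposure_schedule(air_levels[a], 24, 7, duration_days)
          tc <- simulate_exposure(sp, sch, init = y0, dt_out = 24,
                                  rtol = rtol, atol = atol)
          end_of_exposure_concentration(tc)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures,
                          data.frame(subject = s, air = air_levels[a],
                                     message = conditionMessage(res)))
      } else values[s, a] <- res
    }
  }
  summ <- do.call(rbind, lapply(seq_along(air_levels), function(a) {
    v <- values[, a]
    v <- v[is.finite(v)]
    data.frame(air = air_levels[a], t(summarize_distribution(v)))
  }))
  structure(list(values = values, summary = summ, n = n, seed = seed,
                 air_levels = air_levels, failures = failures),
            class = "mn_population")
}

#' Default log-spaced air concentration grid
#'
#' Spans the inhalation reference concentration (0.00005 mg/m^3) to 0.5
#' mg/m^3.
#'
#' @param n_levels number of grid points.
#' @return numeric vector of air concentrations (mg/m^3).
#' @export
default_air_grid <- function(n_levels = 9) {
  exp(seq(log(5e-5), log(0.5), length.out = n_levels))
}

#' @export
print.mn_population <- function(x, ...) {
  cat("<mn_population> n =", x$n, "seed =", x$seed, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
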