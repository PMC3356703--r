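# Shared fixtures: a minimal two-compartment system embedded in the full
# model (blood + brain target, everything else inert), species sets cached
# per session, and a fixed-step RK4 integrator used as a solver oracle.

species_cache <- new.env(parent = emptyenv())

cached_species <- function(species) {
  if (is.null(species_cache[[species]]))
    species_cache[[species]] <- load_species_defaults(species)
  species_cache[[species]]
}

# Blood (1000 g) exchanging with one binding tissue (globus pallidus,
# 100 g, b_max 1 ug/g so total capacity 100 ug); all other compartments
# carry mass but no kinetics.
make_two_compartment <- function(k_in = 1, k_out = 0.5, k_a = 0.01,
                                 k_d = 0.001) {
  nm <- mn_compartments("globus_pallidus")
  cm <- do.call(rbind, lapply(nm, function(n) tissue_params(n, mass = 1)))
  cm$mass[cm$name == "blood"] <- 1000
  i <- match("globus_pallidus", cm$name)
  cm$mass[i] <- 100
  cm$q_blood[i] <- 2
  cm$k_in[i] <- k_in
  cm$k_out[i] <- k_out
  cm$b_max[i] <- 1
  cm$k_a[i] <- k_a
  cm$k_d[i] <- k_d
  species_params(
    "toy2", 1, model_spec("toy2", cm, q_c = 10, q_p = 1),
    dep = deposition_params(0, 0, 0, 0, 0),
    gut = gut_params(1e-9, 1e-3, K_inh = 1e9, n_inh = 1, k_slough = 0,
                     k_blood = 0),
    bile = biliary_params(0),
    diet_mg_per_day = 0)
}

two_compartment_state <- function(a_blood = 2, a_free = 5, a_bound = 20) {
  y <- numeric(31)
  names(y) <- c(paste0("free.", mn_compartments("globus_pallidus")),
                paste0("bound.", mn_compartments("globus_pallidus")),
                "cum_intake", "cum_fecal", "cum_bile")
  y[["free.blood"]] <- a_blood
  y[["free.globus_pallidus"]] <- a_free
  y[["bound.globus_pallidus"]] <- a_bound
  y
}

# Classic fixed-step RK4 over the reference R right-hand side.
rk4_integrate <- function(params, y0, t_end, dt, air = 0,
                          exposure_on = FALSE, diet_ug_h = 0) {
  y <- unname(y0)
  n <- ceiling(t_end / dt)
  f <- function(y) unname(evaluate_rhs(0, pmax(y, 0), params, air,
                                       exposure_on, diet_ug_h))
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Synthetic steady-state anchor table for the calibration recovery study.
recovery_anchors <- function(true_set, diets = c(0.5, 1, 2.25, 9),
                             tissues = c("striatum", "liver"),
                             noise_cv = 0, seed = NULL) {
  anchors <- list()
  for (d in diets) for (ts in tissues) {
    obs <- predict_anchor(true_set,
                          calibration_anchor("rat", ts, 1,
                                             diet_mg_per_day = d))
    anchors[[length(anchors) + 1]] <-
      calibration_anchor("rat", ts, obs, diet_mg_per_day = d)
  }
  if (noise_cv > 0) {
    stopifnot(!is.null(seed))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sigma <- sqrt(log(1 + noise_cv^2))
    anchors <- lapply(anchors, function(a) {
      a$observed <- a$observed * exp(rnorm(1, 0, sigma))
      a
    })
  }
  anchors
}
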