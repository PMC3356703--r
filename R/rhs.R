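# Reference implementation of the model right-hand side in plain R.
# simulate_exposure() uses the compiled equivalent in src/mn_rhs.c by
# default; the two are asserted equal in the test suite.

#' Evaluate the model right-hand side
#'
#' Computes the time derivative of the full state vector: free Mn per
#' compartment, bound Mn per compartment, and the cumulative intake, fecal
#' and biliary counters.  For each binding tissue with free concentration
#' `Cf = a_free/mass` the binding rate is
#' `bind = k_a * Cf * (b_max*mass - a_bound) - k_d * a_bound`, free Mn
#' exchanges with blood as `k_in * C_blood - k_out * Cf` (flows in L/h act
#' on concentrations in ug/L), and the route fluxes of the
#' uptake/elimination module are added to the affected compartments.  The
#' sum of all compartment derivatives equals intake rate minus fecal output
#' rate exactly.
#'
#' @param t time (h); the system is autonomous within an exposure segment.
#' @param state numeric state vector as produced by the simulator (length
#'   31, see [mn_compartments()] for the order).
#' @param params an `mn_species` parameter set.
#' @param air air Mn concentration (ug/L).
#' @param exposure_on logical, whether inhalation is active.
#' @param diet_ug_h dietary input rate (ug/h).
#' @return named numeric derivative vector, same length as `state`.
#' @export
evaluate_rhs <- function(t, state, params, air = 0, exposure_on = FALSE,
                         diet_ug_h = 0) {
  stopifnot(inherits(params, "mn_species"))
  if (length(state) != N_STATE)
    stop("state must have length ", N_STATE)
  if (any(state[seq_len(2 * N_CMT)] < 0))
    stop("negative state component")
  cm <- params$model$compartments
  nm <- cm$name
  af <- state[seq_len(N_CMT)]
  ab <- state[N_CMT + seq_len(N_CMT)]
  btot <- cm$b_max * cm$mass
  cf <- af / cm$mass

  bind <- cm$k_a * cf * (btot - ab) - cm$k_d * ab
  d_af <- -bind
  d_ab <- bind

  # diffusional exchange with blood (flows L/h on ug/L = 1000 * ug/g)
  kin_eff <- 1000 * pmin(cm$k_in, ifelse(cm$q_blood > 0, cm$q_blood,
                                         cm$k_in))
  kout_p <- 1000 * cm$k_out
  perf <- !(nm %in% c("blood", "gut_lumen"))
  ex <- ifelse(perf, kin_eff * cf[1] - kout_p * cf, 0)
  d_af <- d_af + ex
  d_af[1] <- d_af[1] - sum(ex)

  # epithelial absorption to blood
  i_ep <- match(EPITHELIA, nm)
  kabs <- c(params$gut$k_blood,
            params$dep$k_epith_absorb[c("lung", "olfactory", "respiratory")])
  fab <- kabs * af[i_ep]
  d_af[i_ep] <- d_af[i_ep] - fab
  d_af[1] <- d_af[1] + sum(fab)

  # inhalation deposition
  depf <- inhaled_deposition_rates(air, params$model$q_p, params$dep,
                                   isTRUE(exposure_on) && air > 0)
  i_dep <- match(names(depf), nm)
  d_af[i_dep] <- d_af[i_dep] + depf

  # olfactory epithelium -> olfactory bulb
  i_olf <- match("olfactory_epithelium", nm)
  i_bulb <- match("olfactory_bulb", nm)
  f_olf <- olfactory_transport_flux(af[i_olf], params$dep$k_olf_transport)
  d_af[i_olf] <- d_af[i_olf] - f_olf
  d_af[i_bulb] <- d_af[i_bulb] + f_olf

  # gut lumen: diet in, saturable uptake, fecal transit
  i_lum <- match("gut_lumen", nm)
  i_gep <- match("gut_epithelium", nm)
  f_gabs <- gut_absorption_flux(af[i_lum], params$gut)
  f_fec <- params$gut$k_fec * af[i_lum]
  d_af[i_lum] <- d_af[i_lum] + diet_ug_h - f_gabs - f_fec
  d_af[i_gep] <- d_af[i_gep] + f_gabs

  # enterocyte sloughing to feces
  f_slough <- enterocyte_sloughing_flux(af[i_gep], params$gut$k_slough)
  d_af[i_gep] <- d_af[i_gep] - f_slough

  # inducible biliary excretion, liver -> gut lumen (or feces)
  i_liv <- match("liver", nm)
  f_bile <- biliary_excretion_flux(cf[i_liv], params$bile)
  d_af[i_liv] <- d_af[i_liv] - f_bile
  if (params$enterohepatic) {
    d_af[i_lum] <- d_af[i_lum] + f_bile
    d_fec_bile <- 0
  } else {
    d_fec_bile <- f_bile
  }

  d <- c(d_af, d_ab,
         diet_ug_h + sum(depf),
         f_fec + f_slough + d_fec_bile,
         f_bile)
  stats::setNames(d, names(state))
}

# RHS closure over packed parameters, in deSolve's func signature, for the
# pure-R integration path.
rhs_r_func <- function(params) {
  force(params)
  function(t, y, p) {
    y <- pmax(y, 0)  # adaptive solvers may probe marginally negative values
    list(unname(evaluate_rhs(t, y, params, air = p[["air"]],
                             exposure_on = p[["exposure_on"]] > 0,
                             diet_ug_h = p[["diet"]])))
  }
}

# Direct call into the compiled right-hand side (tests, Newton solver).
rhs_compiled <- function(state, parms) {
  .Call(mnpbpk_rhs_call, as.numeric(state), as.numeric(parms))
}
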