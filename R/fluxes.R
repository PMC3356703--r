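# Route-specific uptake and elimination fluxes.  These small functions are
# the single definition of each flux law; the reference right-hand side in
# evaluate_rhs() is built from them and the compiled solver mirrors them.

#' Inhaled deposition rates on the respiratory epithelia
#'
#' While exposure is on, inhaled Mn `air_conc * q_p` (ug/h) deposits on the
#' nasal olfactory, nasal respiratory and lung epithelia according to the
#' lumped deposition fractions; the remainder is exhaled and never enters
#' the body.
#'
#' @param air_conc air Mn concentration (ug/L; 1 mg/m^3 = 1 ug/L).
#' @param q_p pulmonary ventilation (L/h), must be positive while exposure
#'   is on.
#' @param dep a [deposition_params()] object.
#' @param exposure_on logical flag from the exposure schedule.
#' @return named numeric vector of deposition fluxes (ug/h) for
#'   `olfactory_epithelium`, `respiratory_epithelium`, `lung_epithelium`.
#' @export
inhaled_deposition_rates <- function(air_conc, q_p, dep, exposure_on) {
  stopifnot(inherits(dep, "mn_deposition"), air_conc >= 0)
  if (!isTRUE(exposure_on))
    return(c(olfactory_epithelium = 0, respiratory_epithelium = 0,
             lung_epithelium = 0))
  if (q_p <= 0) stop("q_p must be > 0 while exposure is on")
  d <- air_conc * q_p
  c(olfactory_epithelium = dep$f_nasal_olf * d,
    respiratory_epithelium = dep$f_nasal_resp * d,
    lung_epithelium = dep$f_pulm * d)
}

#' Direct olfactory transport flux to the olfactory bulb
#'
#' A small fraction of the Mn deposited on the olfactory epithelium is
#' delivered directly to the olfactory bulb rather than absorbed into the
#' systemic circulation.
#'
#' @param a_olf_epith free Mn amount in the olfactory epithelium (ug).
#' @param k_olf_transport transport rate (h^-1).
#' @return flux (ug/h) into the olfactory bulb.
#' @export
olfactory_transport_flux <- function(a_olf_epith, k_olf_transport) {
  if (a_olf_epith < 0) stop("amount must be >= 0")
  k_olf_transport * a_olf_epith
}

#' Dietary input rate into the gut lumen
#'
#' Diet is delivered continuously (all study designs are 90 days or
#' longer, so meal structure is irrelevant): `mg/day * 1000 / 24` ug/h.
#' The diet may be given either directly in mg/day or as a feed
#' concentration in ppm together with a food intake in g/day, but not both.
#'
#' @param schedule an [exposure_schedule()] object.
#' @param t time (h); present for interface symmetry, the rate is constant.
#' @return dietary input rate (ug/h).
#' @export
dietary_input_rate <- function(schedule, t = 0) {
  stopifnot(inherits(schedule, "mn_schedule"))
  schedule$diet_ug_h
}

#' Saturable gut lumen-to-epithelium absorption flux
#'
#' Uptake is first order at trace lumen amounts (`k_abs * a`) and is
#' inhibited by a Hill term as the lumen amount rises, reproducing the
#' fall in the absorbed dietary fraction with increasing Mn intake.
#'
#' @param a_lumen Mn amount in the gut lumen (ug).
#' @param gut a [gut_params()] object.
#' @return absorption flux (ug/h) from lumen to epithelium.
#' @export
gut_absorption_flux <- function(a_lumen, gut) {
  stopifnot(inherits(gut, "mn_gut"))
  if (a_lumen < 0) stop("lumen amount must be >= 0")
  gut$k_abs * a_lumen / (1 + (a_lumen / gut$K_inh)^gut$n_inh)
}

#' Enterocyte sloughing flux
#'
#' Gut epithelial Mn carried by shed enterocytes is excreted in feces
#' without entering the systemic circulation.
#'
#' @param a_epith Mn amount in the gut epithelium (ug).
#' @param k_slough sloughing rate (h^-1).
#' @return flux (ug/h) from epithelium to feces.
#' @export
enterocyte_sloughing_flux <- function(a_epith, k_slough) {
  if (a_epith < 0) stop("amount must be >= 0")
  k_slough * a_epith
}

#' Inducible biliary excretion flux
#'
#' Liver free Mn is cleared into the gut lumen at the basal biliary
#' clearance multiplied by a Hill induction factor that rises from 1 at
#' trace concentrations to `1 + i_max` at high liver Mn.
#'
#' @param cf_liver liver free Mn concentration (ug/g).
#' @param bil a [biliary_params()] object.
#' @return biliary flux (ug/h) from liver to gut lumen.
#' @export
biliary_excretion_flux <- function(cf_liver, bil) {
  stopifnot(inherits(bil, "mn_biliary"))
  if (cf_liver < 0) stop("concentration must be >= 0")
  f_ind <- biliary_induction_factor(cf_liver, bil)
  1000 * bil$k_bile_c * f_ind * cf_liver
}

#' Biliary induction factor
#'
#' @param cf_liver liver free Mn concentration (ug/g).
#' @param bil a [biliary_params()] object.
#' @return dimensionless factor in `[1, 1 + i_max]`.
#' @export
biliary_induction_factor <- function(cf_liver, bil) {
  if (bil$i_max <= 0 || cf_liver <= 0) return(1)
  hn <- (cf_liver / bil$c50_ind)^bil$n_ind
  if (!is.finite(hn) || hn > 1e15) return(1 + bil$i_max)
  1 + bil$i_max * hn / (1 + hn)
}
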