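# Species parameter library: reference sets for adult rat, rhesus monkey
# and adult human, YAML (de)serialization, and cross-species scaling rules.

#' Allometric scaling of clearances and diffusional fluxes
#'
#' `value = value_ref * (bw / bw_ref)^exponent`.  Biliary clearance and the
#' brain diffusional flux coefficients are extrapolated across species (and
#' across sampled body weights in the Monte Carlo module) with the default
#' exponent 0.75.
#'
#' @param value_ref reference value.
#' @param bw_ref reference body weight (kg).
#' @param bw target body weight (kg).
#' @param exponent allometric exponent (default 0.75; 0 gives a
#'   species-invariant constant).
#' @return scaled value.
#' @export
allometric_scale <- function(value_ref, bw_ref, bw, exponent = 0.75) {
  if (bw_ref <= 0 || bw <= 0) stop("body weights must be > 0")
  value_ref * (bw / bw_ref)^exponent
}

#' Scale a tissue binding capacity to a new tissue mass
#'
#' Binding capacities are scaled to tissue volume: the per-gram capacity
#' `b_max` is preserved and the total capacity is `b_max * mass` (ug).
#'
#' @param b_max_ref per-gram capacity (ug/g) of the reference tissue.
#' @param mass_ref reference tissue mass (g); validated only.
#' @param mass target tissue mass (g).
#' @return total binding capacity (ug) of the target tissue.
#' @export
scale_binding_capacity <- function(b_max_ref, mass_ref, mass) {
  if (mass_ref <= 0 || mass <= 0) stop("tissue masses must be > 0")
  b_max_ref * mass
}

#' Load a packaged species parameter set
#'
#' Returns the calibrated reference parameter set shipped with the package
#' for the adult rat, rhesus monkey or adult human.  Rest-of-body mass and
#' blood flow are stored as the residuals of body weight and cardiac
#' output.  Every parameter carries a provenance note (calibrated against
#' the packaged anchors vs assumed physiology).
#'
#' @param species one of `"rat"`, `"monkey"`, `"human"`.
#' @return an `mn_species` parameter set.
#' @export
load_species_defaults <- function(species) {
  supported <- c("rat", "monkey", "human")
  if (!is.character(species) || length(species) != 1L ||
      !(species %in% supported))
    stop("unknown species '", species, "'; supported species: ",
         paste(supported, collapse = ", "))
  path <- system.file("extdata", paste0("params_", species, ".yaml"),
                      package = "mnpbpk", mustWork = TRUE)
  species_from_yaml(path)
}

#' Read a species parameter set from a YAML file
#'
#' @param path file path of a parameter set written by
#'   [species_to_yaml()].
#' @return an `mn_species` parameter set.
#' @export
species_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  species_from_list(y)
}

species_from_list <- function(y) {
  need <- c("species", "body_weight", "q_c", "q_p", "diet_mg_per_day",
            "compartments", "dep", "gut", "bile")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("parameter set lacks fields: ", paste(missing, collapse = ", "))
  cm <- do.call(rbind, lapply(names(y$compartments), function(nm) {
    do.call(tissue_params, c(list(name = nm), y$compartments[[nm]]))
  }))
  dep <- do.call(deposition_params, within(y$dep, {
    k_epith_absorb <- unlist(k_epith_absorb)
  }))
  species_params(
    species = y$species, body_weight = y$body_weight,
    model = model_spec(y$species, cm, q_c = y$q_c, q_p = y$q_p),
    dep = dep,
    gut = do.call(gut_params, y$gut),
    bile = do.call(biliary_params, y$bile),
    diet_mg_per_day = y$diet_mg_per_day,
    enterohepatic = !isFALSE(y$enterohepatic),
    provenance = unlist(y$provenance))
}

#' Write a species parameter set to a YAML file
#'
#' The written file round-trips through [species_from_yaml()] to an
#' identical parameter set.
#'
#' @param params an `mn_species` parameter set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
species_to_yaml <- function(params, path) {
  stopifnot(inherits(params, "mn_species"))
  cm <- params$model$compartments
  comp <- lapply(seq_len(nrow(cm)), function(i) {
    as.list(cm[i, setdiff(names(cm), "name")])
  })
  names(comp) <- cm$name
  y <- list(
    species = params$species,
    body_weight = params$body_weight,
    q_c = params$model$q_c,
    q_p = params$model$q_p,
    diet_mg_per_day = params$diet_mg_per_day,
    enterohepatic = params$enterohepatic,
    compartments = comp,
    dep = list(f_nasal_olf = params$dep$f_nasal_olf,
               f_nasal_resp = params$dep$f_nasal_resp,
               f_pulm = params$dep$f_pulm,
               k_olf_transport = params$dep$k_olf_transport,
               k_epith_absorb = as.list(params$dep$k_epith_absorb)),
    gut = params$gut[c("k_abs", "k_fec", "K_inh", "n_inh", "k_slough",
                       "k_blood")],
    bile = unclass(params$bile),
    provenance = as.list(params$provenance))
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}
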