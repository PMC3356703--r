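# Parameter objects: tissues, model specification, route parameter blocks,
# and the packed numeric parameter vector shared with the compiled solver.

#' Canonical compartment order of the manganese PBPK model
#'
#' The model always carries these fourteen compartments, in this order.  The
#' brain target compartment is called `"striatum"` in the rat and
#' `"globus_pallidus"` in the monkey and human; [mn_compartments()] reports
#' the names for a given target label.
#'
#' @param target name of the brain target compartment, either `"striatum"`
#'   or `"globus_pallidus"`.
#' @return character vector of fourteen compartment names.
#' @export
mn_compartments <- function(target = "globus_pallidus") {
  target <- match.arg(target, c("globus_pallidus", "striatum"))
  c("blood", "liver", "gut_lumen", "gut_epithelium", "lung_epithelium",
    "olfactory_epithelium", "respiratory_epithelium", "olfactory_bulb",
    target, "cerebellum", "pituitary", "bone", "kidney", "rest_of_body")
}

EPITHELIA <- c("gut_epithelium", "lung_epithelium",
               "olfactory_epithelium", "respiratory_epithelium")

#' Tissue-level kinetic parameters
#'
#' One row of the compartment table: mass, perfusion, asymmetric diffusional
#' exchange coefficients and saturable binding constants.  Tissue density is
#' fixed at 1 g/mL so that `mass` in g doubles as volume in mL and ug/g
#' equals ug/mL.
#'
#' @param name compartment name.
#' @param mass tissue mass (g), must be positive.
#' @param q_blood tissue blood flow (L/h).
#' @param k_in diffusional influx coefficient (L/h), applied to the blood
#'   free concentration.  The effective influx is capped at `q_blood` for
#'   perfused tissues: diffusion cannot exceed delivery by blood.
#' @param k_out diffusional efflux coefficient (L/h), applied to the tissue
#'   free concentration.
#' @param b_max binding capacity (ug Mn per g tissue).
#' @param k_a association rate constant (g ug^-1 h^-1).
#' @param k_d dissociation rate constant (h^-1).
#' @param k_absorb first-order absorption rate to systemic blood (h^-1);
#'   only meaningful for epithelial compartments, zero elsewhere.
#' @return a `data.frame` with one row, suitable for `rbind()` into a
#'   compartment table.
#' @export
tissue_params <- function(name, mass, q_blood = 0, k_in = 0, k_out = 0,
                          b_max = 0, k_a = 0, k_d = 0, k_absorb = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(mass = mass, k_in = k_in, k_out = k_out,
            b_max = b_max, k_a = k_a, k_d = k_d, k_absorb = k_absorb)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("tissue '", name, "': all parameters must be finite and >= 0")
  # q_blood may be NA for rest_of_body (filled with the residual flow)
  if (!is.na(q_blood) && (!is.finite(q_blood) || q_blood < 0))
    stop("tissue '", name, "': q_blood must be >= 0 (or NA for residual)")
  if (mass <= 0)
    stop("tissue '", name, "': mass must be > 0")
  data.frame(name = name, mass = mass, q_blood = q_blood, k_in = k_in,
             k_out = k_out, b_max = b_max, k_a = k_a, k_d = k_d,
             k_absorb = k_absorb, stringsAsFactors = FALSE)
}

#' Inhalation deposition and olfactory-transport parameters
#'
#' Inhaled Mn is deposited on the nasal olfactory, nasal respiratory and
#' lung epithelia as lumped fractions of the inhaled amount; the remainder
#' is exhaled.  Deposited Mn is absorbed into systemic blood at first-order
#' rate `k_epith_absorb`, except for a small fraction in the olfactory
#' epithelium that is transported directly to the olfactory bulb at
#' `k_olf_transport`.
#'
#' @param f_nasal_olf,f_nasal_resp,f_pulm deposition fractions (sum <= 1).
#' @param k_olf_transport olfactory epithelium to olfactory bulb transport
#'   rate (h^-1).
#' @param k_epith_absorb epithelium to blood absorption rate (h^-1); either
#'   a single rate or a named vector with entries `lung`, `olfactory`,
#'   `respiratory`.
#' @return an object of class `mn_deposition`.
#' @export
deposition_params <- function(f_nasal_olf, f_nasal_resp, f_pulm,
                              k_olf_transport, k_epith_absorb) {
  fr <- c(f_nasal_olf, f_nasal_resp, f_pulm)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12)
    stop("deposition fractions must be >= 0 and sum to at most 1")
  if (length(k_epith_absorb) == 1L && is.null(names(k_epith_absorb)))
    k_epith_absorb <- c(lung = unname(k_epith_absorb),
                        olfactory = unname(k_epith_absorb),
                        respiratory = unname(k_epith_absorb))
  need <- c("lung", "olfactory", "respiratory")
  if (!all(need %in% names(k_epith_absorb)))
    stop("k_epith_absorb must name rates for: ",
         paste(need, collapse = ", "))
  if (any(k_epith_absorb < 0) || k_olf_transport < 0)
    stop("absorption and transport rates must be >= 0")
  structure(list(f_nasal_olf = f_nasal_olf, f_nasal_resp = f_nasal_resp,
                 f_pulm = f_pulm, f_exhaled = 1 - sum(fr),
                 k_olf_transport = k_olf_transport,
                 k_epith_absorb = k_epith_absorb[need]),
            class = "mn_deposition")
}

#' Gastrointestinal uptake parameters
#'
#' Dietary Mn enters the gut lumen and is taken up by the gut epithelium at
#' a saturable rate; uptake is inhibited as the lumen Mn amount rises, which
#' produces the dose-dependent fall of the absorbed fraction (Fdietup).
#' Epithelial Mn either absorbs to blood (`k_blood`) or is lost to feces by
#' enterocyte sloughing (`k_slough`).
#'
#' @param k_abs basal lumen-to-epithelium uptake rate (h^-1).
#' @param k_fec lumen-to-feces transit rate (h^-1).
#' @param K_inh lumen amount at half-maximal uptake inhibition (ug).
#' @param n_inh Hill exponent of the uptake inhibition (>= 1).
#' @param k_slough enterocyte sloughing rate (h^-1).
#' @param k_blood gut epithelium to blood absorption rate (h^-1).
#' @return an object of class `mn_gut` with the derived basal absorbed
#'   fraction `f_dietup0 = k_abs / (k_abs + k_fec)`.
#' @export
gut_params <- function(k_abs, k_fec, K_inh, n_inh = 1, k_slough, k_blood) {
  if (K_inh <= 0) stop("K_inh must be > 0")
  if (n_inh < 1) stop("n_inh must be >= 1")
  if (any(c(k_abs, k_fec, k_slough, k_blood) < 0))
    stop("gut rates must be >= 0")
  f0 <- k_abs / (k_abs + k_fec)
  if (!is.finite(f0) || f0 <= 0 || f0 >= 1)
    stop("basal absorbed fraction k_abs/(k_abs+k_fec) must lie in (0, 1)")
  structure(list(k_abs = k_abs, k_fec = k_fec, f_dietup0 = f0,
                 K_inh = K_inh, n_inh = n_inh, k_slough = k_slough,
                 k_blood = k_blood),
            class = "mn_gut")
}

#' Inducible biliary excretion parameters
#'
#' Liver free Mn is cleared into the gut lumen at clearance `k_bile_c`,
#' multiplied by a Hill induction factor `1 + i_max * C^n / (c50^n + C^n)`
#' of the liver free concentration `C`, so elimination accelerates as the
#' liver Mn burden rises.
#'
#' @param k_bile_c basal biliary clearance (L/h).
#' @param i_max maximal fold-induction above basal (>= 0).
#' @param c50_ind liver free concentration at half-maximal induction (ug/g).
#' @param n_ind Hill exponent (>= 1).
#' @return an object of class `mn_biliary`.
#' @export
biliary_params <- function(k_bile_c, i_max = 0, c50_ind = 1, n_ind = 1) {
  if (k_bile_c < 0 || i_max < 0) stop("k_bile_c and i_max must be >= 0")
  if (c50_ind <= 0) stop("c50_ind must be > 0")
  if (n_ind < 1) stop("n_ind must be >= 1")
  structure(list(k_bile_c = k_bile_c, i_max = i_max, c50_ind = c50_ind,
                 n_ind = n_ind),
            class = "mn_biliary")
}

#' Whole-body model specification
#'
#' Assembles the compartment table with cardiac output, pulmonary
#' ventilation and exposure-route flags into a validated model structure.
#' Compartments are reordered to the canonical order of
#' [mn_compartments()]; the rest-of-body blood flow may be given as `NA` to
#' be filled with the residual `q_c - sum(q_blood)`.
#'
#' @param species species label (free text, e.g. `"human"`).
#' @param compartments `data.frame` with the columns of [tissue_params()],
#'   one row per compartment, containing all canonical compartments.
#' @param q_c cardiac output (L/h).
#' @param q_p pulmonary ventilation (L/h).
#' @param oral,inhalation logical route flags.
#' @return an object of class `mn_model`.
#' @export
model_spec <- function(species, compartments, q_c, q_p,
                       oral = TRUE, inhalation = TRUE) {
  stopifnot(is.data.frame(compartments), q_c > 0, q_p > 0)
  if (anyDuplicated(compartments$name))
    stop("compartment names must be unique")
  target <- intersect(c("globus_pallidus", "striatum"), compartments$name)
  if (length(target) != 1L)
    stop("exactly one brain target compartment (globus_pallidus or ",
         "striatum) is required")
  want <- mn_compartments(target)
  missing <- setdiff(want, compartments$name)
  if (length(missing))
    stop("missing compartments: ", paste(missing, collapse = ", "))
  extra <- setdiff(compartments$name, want)
  if (length(extra))
    stop("unknown compartments: ", paste(extra, collapse = ", "))
  compartments <- compartments[match(want, compartments$name), ]
  rownames(compartments) <- NULL

  irest <- match("rest_of_body", compartments$name)
  others <- sum(compartments$q_blood[-irest], na.rm = TRUE)
  if (is.na(compartments$q_blood[irest]))
    compartments$q_blood[irest] <- q_c - others
  if (compartments$q_blood[irest] < 0 || others > q_c + 1e-9)
    stop("tissue blood flows exceed cardiac output; residual rest-of-body ",
         "flow would be negative")
  structure(list(species = species, compartments = compartments,
                 target = target, q_c = q_c, q_p = q_p,
                 oral = isTRUE(oral), inhalation = isTRUE(inhalation)),
            class = "mn_model")
}

#' Complete species parameter set
#'
#' Bundles the model structure with the route parameter blocks into the
#' unit handed to [simulate_exposure()], [apply_scenario()] and the
#' calibration functions.
#'
#' @param species one of `"rat"`, `"monkey"`, `"human"` (or a free label
#'   for synthetic sets).
#' @param body_weight body weight (kg).
#' @param model an [model_spec()] object.
#' @param dep a [deposition_params()] object.
#' @param gut a [gut_params()] object.
#' @param bile a [biliary_params()] object.
#' @param diet_mg_per_day default dietary Mn intake (mg/day) used when a
#'   schedule does not specify its own diet.
#' @param enterohepatic logical; if `TRUE` (default) biliary Mn re-enters
#'   the gut lumen and may be reabsorbed, otherwise it is excreted
#'   directly in feces.
#' @param provenance named character vector of free-text provenance notes
#'   ("calibrated" vs "assumed") per parameter.
#' @return an object of class `mn_species`.
#' @export
species_params <- function(species, body_weight, model, dep, gut, bile,
                           diet_mg_per_day, enterohepatic = TRUE,
                           provenance = character()) {
  stopifnot(inherits(model, "mn_model"), inherits(dep, "mn_deposition"),
            inherits(gut, "mn_gut"), inherits(bile, "mn_biliary"),
            body_weight > 0, diet_mg_per_day >= 0)
  structure(list(species = species, body_weight = body_weight,
                 model = model, dep = dep, gut = gut, bile = bile,
                 diet_mg_per_day = diet_mg_per_day,
                 enterohepatic = isTRUE(enterohepatic),
                 provenance = provenance),
            class = "mn_species")
}

#' @export
print.mn_species <- function(x, ...) {
  cat("<mn_species>", x$species, "\n")
  cat("  body weight:", x$body_weight, "kg; q_c:", x$model$q_c,
      "L/h; q_p:", x$model$q_p, "L/h\n")
  cat("  diet:", x$diet_mg_per_day, "mg Mn/day; target tissue:",
      x$model$target, "\n")
  cat("  compartments:", nrow(x$model$compartments), "\n")
  invisible(x)
}

# ---- packed parameter vector (layout shared with src/mn_rhs.c) -----------

N_CMT <- 14L
N_PAR <- 118L
N_STATE <- 2L * N_CMT + 3L

#' Pack a species parameter set into the solver parameter vector
#'
#' Internal layout shared with the compiled right-hand side.  Flows and
#' clearances are converted from L/h to g/h (factor 1000, density 1 g/mL)
#' and the diffusional influx of perfused tissues is capped at the tissue
#' blood flow.
#'
#' @param params an `mn_species` object.
#' @param air air Mn concentration (ug/L, numerically equal to mg/m^3).
#' @param exposure_on 1 while inhalation is active, else 0.
#' @param diet_ug_h dietary input rate into the gut lumen (ug/h).
#' @return numeric vector of length 118.
#' @keywords internal
pack_parms <- function(params, air = 0, exposure_on = 0, diet_ug_h = 0) {
  cm <- params$model$compartments
  dep <- params$dep
  gut <- params$gut
  bil <- params$bile

  kin_eff <- pmin(cm$k_in, ifelse(cm$q_blood > 0, cm$q_blood, cm$k_in))
  kabs <- numeric(N_CMT)
  kabs[match("gut_epithelium", cm$name)] <- gut$k_blood
  kabs[match("lung_epithelium", cm$name)] <- dep$k_epith_absorb[["lung"]]
  kabs[match("olfactory_epithelium", cm$name)] <-
    dep$k_epith_absorb[["olfactory"]]
  kabs[match("respiratory_epithelium", cm$name)] <-
    dep$k_epith_absorb[["respiratory"]]

  c(params$model$q_c, params$model$q_p, air, exposure_on, diet_ug_h,
    dep$f_nasal_olf, dep$f_nasal_resp, dep$f_pulm,
    dep$k_olf_transport, gut$k_abs, gut$k_fec, gut$K_inh, gut$n_inh,
    gut$k_slough, 1000 * bil$k_bile_c, bil$i_max, bil$c50_ind, bil$n_ind,
    as.numeric(params$enterohepatic), 0,
    cm$mass, 1000 * kin_eff, 1000 * cm$k_out, cm$b_max * cm$mass,
    cm$k_a, cm$k_d, kabs)
}

state_names <- function(model) {
  nm <- model$compartments$name
  c(paste0("free.", nm), paste0("bound.", nm),
    "cum_intake", "cum_fecal", "cum_bile")
}

zero_state <- function(model) {
  stats::setNames(numeric(N_STATE), state_names(model))
}
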