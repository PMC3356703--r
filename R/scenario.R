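# Scenario modifiers (susceptible subpopulations), dose metrics and
# pharmacokinetic chemical-specific adjustment factors (CSAF).

#' Scenario definition
#'
#' A named set of multiplicative parameter modifiers, optionally with an
#' exposure-schedule override.  Modifier names are parameter paths:
#' `q_c`, `q_p`, `diet`, `dep.<field>`, `gut.<field>`, `bile.<field>`, or
#' `tissue.<compartment>.<column>` (e.g. `tissue.liver.q_blood`).  Unknown
#' paths and non-positive factors are rejected at construction.
#'
#' @param name scenario label.
#' @param modifiers named numeric vector of multiplicative factors.
#' @param schedule optional [exposure_schedule()] override.
#' @return an object of class `mn_scenario`.
#' @export
scenario <- function(name, modifiers = numeric(), schedule = NULL) {
  if (length(modifiers)) {
    if (is.null(names(modifiers)) || any(!nzchar(names(modifiers))))
      stop("modifiers must be named")
    if (any(!is.finite(modifiers)) || any(modifiers <= 0))
      stop("modifier factors must be finite and > 0")
    bad <- names(modifiers)[!vapply(names(modifiers), valid_param_path,
                                    logical(1))]
    if (length(bad))
      stop("unknown parameter path(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(schedule)) stopifnot(inherits(schedule, "mn_schedule"))
  structure(list(name = name, modifiers = modifiers, schedule = schedule),
            class = "mn_scenario")
}

valid_param_path <- function(path) {
  if (path %in% c("q_c", "q_p", "diet")) return(TRUE)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[1] %in% c("dep", "gut", "bile")) {
    fields <- switch(parts[1],
      dep = c("f_nasal_olf", "f_nasal_resp", "f_pulm", "k_olf_transport",
              "k_epith_absorb"),
      gut = c("k_abs", "k_fec", "K_inh", "n_inh", "k_slough", "k_blood"),
      bile = c("k_bile_c", "i_max", "c50_ind", "n_ind"))
    return(parts[2] %in% fields)
  }
  if (length(parts) == 3 && parts[1] == "tissue") {
    cols <- c("mass", "q_blood", "k_in", "k_out", "b_max", "k_a", "k_d",
              "k_absorb")
    return(parts[3] %in% cols)  # compartment checked against the set later
  }
  FALSE
}

#' The hepatobiliary-impairment scenario
#'
#' Moderate hepatobiliary disease: 50% decrease in liver blood flow and a
#' concomitant 50% decrease in biliary excretion.
#'
#' @return an `mn_scenario`.
#' @export
scenario_hepatic_impaired <- function() {
  scenario("hepatic_impaired",
           c("tissue.liver.q_blood" = 0.5, "bile.k_bile_c" = 0.5))
}

#' The aged life-stage scenario
#'
#' 25% decrease in minute volume, reflecting the reported decline of
#' pulmonary function with age.
#'
#' @return an `mn_scenario`.
#' @export
scenario_aged <- function() {
  scenario("aged", c("q_p" = 0.75))
}

#' Apply a scenario to a species parameter set
#'
#' Returns a new parameter set with the multiplicative modifiers applied;
#' the input set is untouched.  Changing a tissue blood flow re-balances
#' the rest-of-body residual flow against cardiac output; a modifier that
#' would make the residual negative is rejected.
#'
#' @param params an `mn_species` parameter set.
#' @param scn an [scenario()] object.
#' @return a modified `mn_species` parameter set.
#' @export
apply_scenario <- function(params, scn) {
  stopifnot(inherits(params, "mn_species"), inherits(scn, "mn_scenario"))
  p <- params
  cm <- p$model$compartments
  for (path in names(scn$modifiers)) {
    f <- scn$modifiers[[path]]
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (path == "q_c") p$model$q_c <- p$model$q_c * f
    else if (path == "q_p") p$model$q_p <- p$model$q_p * f
    else if (path == "diet") p$diet_mg_per_day <- p$diet_mg_per_day * f
    else if (parts[1] %in% c("dep", "gut", "bile")) {
      p[[parts[1]]][[parts[2]]] <- p[[parts[1]]][[parts[2]]] * f
    } else {
      i <- match(parts[2], cm$name)
      if (is.na(i)) stop("unknown compartment in path: ", path)
      cm[i, parts[3]] <- cm[i, parts[3]] * f
    }
  }
  # re-balance rest-of-body residual flow
  irest <- match("rest_of_body", cm$name)
  cm$q_blood[irest] <- NA_real_
  p$model <- model_spec(p$model$species, cm, q_c = p$model$q_c,
                        q_p = p$model$q_p, oral = p$model$oral,
                        inhalation = p$model$inhalation)
  p
}

#' End-of-exposure tissue concentration
#'
#' Total concentration at the final instant inhalation is active; for a
#' continuous schedule (or one with no inhalation) this is the final
#' simulated time.
#'
#' @param tc an `mn_timecourse`.
#' @param tissue compartment name; defaults to the brain target tissue.
#' @return concentration (ug/g).
#' @export
end_of_exposure_concentration <- function(tc, tissue = NULL) {
  stopifnot(inherits(tc, "mn_timecourse"))
  conc <- tissue_concentration(tc, tissue)
  i <- if (any(tc$exposure_on)) max(which(tc$exposure_on))
       else length(tc$times)
  conc[i]
}

#' Average daily AUC of a tissue concentration
#'
#' Trapezoidal integral of the total tissue concentration over the final
#' `window` days of the simulation, divided by the window length in days
#' (ug*h/g/day).
#'
#' @param tc an `mn_timecourse`.
#' @param tissue compartment name; defaults to the brain target tissue.
#' @param window window length (days); default the full simulation.
#' @return average daily AUC (ug*h/g/day).
#' @export
average_daily_auc <- function(tc, tissue = NULL, window = NULL) {
  stopifnot(inherits(tc, "mn_timecourse"))
  t_end <- max(tc$times)
  if (is.null(window)) window <- t_end / 24
  if (window <= 0) stop("window must be > 0")
  if (window * 24 > t_end + 1e-9)
    stop("window (", window, " d) exceeds the simulated duration")
  conc <- tissue_concentration(tc, tissue)
  keep <- tc$times >= t_end - window * 24 - 1e-9
  tt <- tc$times[keep]; cc <- conc[keep]
  auc <- sum(diff(tt) * (cc[-length(cc)] + cc[-1]) / 2)
  auc / window
}

#' Peak tissue concentration
#'
#' @param tc an `mn_timecourse`.
#' @param tissue compartment name; defaults to the brain target tissue.
#' @return maximum total concentration (ug/g) over the output grid.
#' @export
c_max <- function(tc, tissue = NULL) {
  max(tissue_concentration(tc, tissue))
}

#' Percent change from the basal concentration
#'
#' @param exposed exposed concentration (ug/g).
#' @param basal basal concentration (ug/g), must be positive.
#' @return percent change `100 * (exposed - basal) / basal`.
#' @export
percent_change_from_basal <- function(exposed, basal) {
  if (any(basal <= 0)) stop("basal concentration must be > 0")
  100 * (exposed - basal) / basal
}

#' Pharmacokinetic chemical-specific adjustment factor
#'
#' Ratio of an internal dose metric (end-of-exposure concentration, AUC,
#' Cmax) in a potentially susceptible subpopulation to the same metric in
#' the baseline population.  Values above 1 mean the susceptible group
#' attains the higher internal dose.
#'
#' @param metric_susceptible dose metric of the susceptible group.
#' @param metric_baseline dose metric of the baseline group (> 0).
#' @return dimensionless CSAF.
#' @export
compute_csaf <- function(metric_susceptible, metric_baseline) {
  if (any(metric_baseline <= 0)) stop("baseline metric must be > 0")
  metric_susceptible / metric_baseline
}

#' Summarize dose metrics of a time course
#'
#' @param tc an `mn_timecourse`.
#' @param tissue compartment name; defaults to the brain target tissue.
#' @param basal optional basal concentration (ug/g) for the percent
#'   change; defaults to the concentration at the first output time.
#' @return `data.frame` with `end_of_exposure_conc`, `avg_daily_auc`,
#'   `c_max` and `pct_change_from_basal`.
#' @export
dose_metrics <- function(tc, tissue = NULL, basal = NULL) {
  conc <- tissue_concentration(tc, tissue)
  if (is.null(basal)) basal <- conc[1]
  data.frame(
    end_of_exposure_conc = end_of_exposure_concentration(tc, tissue),
    avg_daily_auc = average_daily_auc(tc, tissue),
    c_max = max(conc),
    pct_change_from_basal =
      percent_change_from_basal(end_of_exposure_concentration(tc, tissue),
                                basal))
}
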