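# Packaged calibration/validation anchors: the printed tissue
# concentrations the shipped parameter sets are calibrated against.

#' End time (h) of the n-th exposure day of a schedule
#'
#' Expands the weekly pattern and returns the clock time at which the
#' n-th on-phase ends; used to place sampling times defined in "exposure
#' days" (e.g. 15, 33 or 65 exposure days of a 5 d/wk design).
#'
#' @param schedule an [exposure_schedule()].
#' @param n_exposure_days which exposure day (1-based).
#' @return time (h) since schedule start.
#' @export
exposure_day_end_time <- function(schedule, n_exposure_days) {
  stopifnot(inherits(schedule, "mn_schedule"), n_exposure_days >= 1)
  week <- (n_exposure_days - 1) %/% schedule$days_per_week
  day_in_week <- (n_exposure_days - 1) %% schedule$days_per_week
  (week * 7 + day_in_week) * 24 + schedule$start_time +
    schedule$hours_per_day
}

#' Packaged calibration anchors per species
#'
#' The monkey anchors are the measured rhesus globus pallidus
#' concentrations: basal 0.48 ug/g on a 133 ppm diet, and 1.92 / 2.41 /
#' 2.94 ug/g after 15 / 33 / 65 exposure days of MnSO4 inhalation at 1.5
#' mg Mn/m^3 (6 h/d, 5 d/wk).  The human anchors encode the basal
#' globus pallidus concentration of about 0.5 ug/g (mid normal range)
#' and the end-of-exposure concentration of 0.68 ug/g after one year of
#' occupational exposure at 0.2 mg/m^3 (8 h/d, 5 d/wk).  The rat anchor
#' is a basal striatal concentration of 0.4 ug/g on a 125 ppm diet.
#'
#' @param species one of `"rat"`, `"monkey"`, `"human"`.
#' @return list of [calibration_anchor()] objects.
#' @export
packaged_anchors <- function(species) {
  switch(species,
    monkey = {
      sch <- canned_schedules()$dorman_65day
      c(list(calibration_anchor("monkey", "globus_pallidus", 0.48,
                                provenance = "basal, 133 ppm diet")),
        lapply(seq_along(c(15, 33, 65)), function(i) {
          nd <- c(15, 33, 65)[i]
          obs <- c(1.92, 2.41, 2.94)[i]
          calibration_anchor(
            "monkey", "globus_pallidus", obs, schedule = sch,
            sample_time_h = exposure_day_end_time(sch, nd),
            provenance = sprintf("%d exposure days, 1.5 mg/m^3", nd))
        }))
    },
    human = list(
      calibration_anchor("human", "globus_pallidus", 0.50,
                         provenance = "basal, 2.43 mg/day diet"),
      calibration_anchor("human", "globus_pallidus", 0.68,
                         schedule = canned_schedules()$occupational_human,
                         provenance = "1 yr occupational, 0.2 mg/m^3")),
    rat = list(
      calibration_anchor("rat", "striatum", 0.40,
                         provenance = "basal, 125 ppm diet")),
    stop("unknown species '", species, "'"))
}
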