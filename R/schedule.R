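# Exposure schedules: intermittent inhalation patterns plus continuous
# dietary intake, and their expansion into piecewise-constant segments.

#' Exposure schedule
#'
#' Describes an intermittent inhalation pattern (air concentration,
#' hours/day, days/week, total duration) together with the continuous
#' dietary intake.  Diet is given either directly as `diet_mg_per_day` or
#' as a feed concentration `diet_ppm` with a `food_intake_g_per_day`, but
#' not both; if neither is given the species default diet is used at
#' simulation time.
#'
#' @param air_conc air Mn concentration in mg Mn/m^3 (numerically equal to
#'   ug/L).
#' @param hours_per_day inhalation hours per exposure day, in `[0, 24]`.
#' @param days_per_week exposure days per week, integer in `[1, 7]`.
#' @param duration_days total schedule duration in calendar days (> 0).
#' @param diet_mg_per_day dietary Mn intake (mg/day), optional.
#' @param diet_ppm feed Mn concentration (ppm = mg Mn/kg feed), optional.
#' @param food_intake_g_per_day feed intake (g/day); required with
#'   `diet_ppm`.
#' @param start_time schedule start time offset (h) within the exposure
#'   day; the first exposure window runs from `start_time` to
#'   `start_time + hours_per_day` of each exposure day.
#' @return an object of class `mn_schedule`.
#' @export
exposure_schedule <- function(air_conc, hours_per_day, days_per_week,
                              duration_days, diet_mg_per_day = NULL,
                              diet_ppm = NULL,
                              food_intake_g_per_day = NULL,
                              start_time = 0) {
  if (air_conc < 0) stop("air_conc must be >= 0")
  if (hours_per_day < 0 || hours_per_day > 24)
    stop("hours_per_day must lie in [0, 24]")
  if (days_per_week < 1 || days_per_week > 7)
    stop("days_per_week must lie in [1, 7]")
  if (duration_days <= 0) stop("duration_days must be > 0")
  if (start_time < 0 || start_time + hours_per_day > 24)
    stop("start_time + hours_per_day must fit within a day")
  if (!is.null(diet_mg_per_day) && !is.null(diet_ppm))
    stop("give either diet_mg_per_day or diet_ppm, not both")
  if (!is.null(diet_ppm) && is.null(food_intake_g_per_day))
    stop("diet_ppm requires food_intake_g_per_day")
  diet <- diet_mg_per_day
  if (!is.null(diet_ppm))
    diet <- diet_ppm * food_intake_g_per_day / 1000  # mg/day
  if (!is.null(diet) && diet < 0) stop("diet must be >= 0")
  structure(list(air_conc = air_conc, hours_per_day = hours_per_day,
                 days_per_week = as.integer(days_per_week),
                 duration_days = duration_days,
                 diet_mg_per_day = diet,
                 diet_ug_h = if (is.null(diet)) NULL else diet * 1000 / 24,
                 start_time = start_time),
            class = "mn_schedule")
}

#' Canned exposure schedules used by the packaged scenarios
#'
#' A named library of the exposure designs exercised throughout the
#' package: `occupational_human` (8 h/d, 5 d/wk, 1 yr, default air 0.2
#' mg/m^3, the ACGIH TLV), `occupational_human_90d` (same pattern, 90
#' days), `monkey_subchronic` (6 h/d, 5 d/wk, 90 d), `continuous_365d`
#' (24 h/7 d, 365 d), `monkey_duration_90d` / `monkey_duration_2yr`
#' (24 h/7 d at 0.2 mg/m^3) and `dorman_65day` (6 h/d, 5 d/wk at 1.5
#' mg/m^3 until 65 exposure days have accrued, i.e. 91 calendar days).
#'
#' @param air optional air concentration (mg/m^3) overriding each
#'   schedule's default.
#' @return named list of [exposure_schedule()] objects.
#' @export
canned_schedules <- function(air = NULL) {
  s <- list(
    occupational_human = exposure_schedule(0.2, 8, 5, 365),
    occupational_human_90d = exposure_schedule(0.2, 8, 5, 90),
    monkey_subchronic = exposure_schedule(0.5, 6, 5, 90),
    continuous_365d = exposure_schedule(0.2, 24, 7, 365),
    monkey_duration_90d = exposure_schedule(0.2, 24, 7, 90),
    monkey_duration_2yr = exposure_schedule(0.2, 24, 7, 730),
    dorman_65day = exposure_schedule(1.5, 6, 5, 91)
  )
  if (!is.null(air))
    s <- lapply(s, function(x) { x$air_conc <- air; x })
  s
}

#' Expand a schedule into piecewise-constant exposure segments
#'
#' Deterministically expands the weekly pattern from `start_time` into a
#' table of `(t0, t1, exposure_on)` segments covering `[0, t_end]`;
#' consecutive segments with the same exposure state (nights plus
#' weekends) are merged.
#'
#' @param schedule an [exposure_schedule()] object.
#' @param t_end end time (h); defaults to the schedule duration.
#' @return `data.frame` with columns `t0`, `t1`, `exposure_on`.
#' @export
expand_schedule <- function(schedule, t_end = NULL) {
  stopifnot(inherits(schedule, "mn_schedule"))
  if (is.null(t_end)) t_end <- schedule$duration_days * 24
  if (t_end <= 0) stop("t_end must be > 0")
  hpd <- schedule$hours_per_day
  if (schedule$air_conc == 0 || hpd == 0)
    return(data.frame(t0 = 0, t1 = t_end, exposure_on = FALSE))
  dur_h <- schedule$duration_days * 24
  ndays <- ceiling(min(t_end, dur_h) / 24)
  day <- seq_len(ndays) - 1
  exposed_day <- (day %% 7) < schedule$days_per_week
  on0 <- day * 24 + schedule$start_time
  on1 <- pmin(on0 + hpd, dur_h)  # exposure stops at schedule end
  on0 <- on0[exposed_day]
  on1 <- on1[exposed_day]
  keep <- on0 < min(t_end, dur_h) & on1 > on0
  on0 <- on0[keep]; on1 <- pmin(on1[keep], t_end)

  bounds <- sort(unique(c(0, on0, on1, t_end)))
  bounds <- bounds[bounds <= t_end]
  t0 <- bounds[-length(bounds)]
  t1 <- bounds[-1]
  on <- vapply(t0, function(a) any(on0 <= a & on1 > a), logical(1))
  # merge consecutive segments with equal state
  grp <- cumsum(c(TRUE, on[-1] != on[-length(on)]))
  data.frame(t0 = as.numeric(tapply(t0, grp, min)),
             t1 = as.numeric(tapply(t1, grp, max)),
             exposure_on = as.logical(tapply(on, grp, any)),
             row.names = NULL)
}
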