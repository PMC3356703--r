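# Run configuration: strict parsing of YAML/JSON configs, default
# resolution, and artifact serialization.

RUNCONFIG_KEYS <- c("species", "overrides", "schedule", "scenario",
                    "out_dir", "seed", "solver", "monte_carlo")
SOLVER_KEYS <- c("rtol", "atol", "dt_out", "method")
MC_KEYS <- c("n", "air_levels", "duration_days")
SCHEDULE_KEYS <- c("air_conc", "hours_per_day", "days_per_week",
                   "duration_days", "diet_mg_per_day", "diet_ppm",
                   "food_intake_g_per_day", "start_time")

#' Parse a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension, or YAML for
#' inline text) into a validated run configuration with all defaults
#' resolved.  Unknown keys are rejected with a path-qualified message;
#' a seed is mandatory when a Monte Carlo block is present.
#'
#' Recognized keys: `species` (rat/monkey/human), `overrides` (named
#' multiplicative factors on parameter paths), `schedule` (a name from
#' [canned_schedules()] or an inline schedule block), `scenario` (name:
#' `hepatic_impaired`, `aged`, or `none`), `out_dir`, `seed`, `solver`
#' (`rtol`, `atol`, `dt_out`, `method`) and `monte_carlo` (`n`,
#' `air_levels`, `duration_days`).
#'
#' @param x path to a config file, or a YAML string.
#' @return an object of class `mn_runconfig` with resolved defaults and
#'   a `defaulted` attribute listing which fields fell back to defaults.
#' @export
parse_config <- function(x) {
  # keep YAML 1.1 boolean-like scalars (notably a key spelled "n") as text
  keep <- list(`bool#no` = function(v) v, `bool#yes` = function(v) v)
  if (length(x) == 1 && file.exists(x)) {
    cfg <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x, handlers = keep)
  } else {
    cfg <- yaml::read_yaml(text = paste(x, collapse = "\n"),
                           handlers = keep)
  }
  if (!is.list(cfg)) stop("config must be a mapping")
  check_keys(cfg, RUNCONFIG_KEYS, "config")

  if (is.null(cfg$species)) stop("config$species is required")
  supported <- c("rat", "monkey", "human")
  if (!cfg$species %in% supported)
    stop("config$species: unknown species '", cfg$species, "'")

  defaulted <- character()
  if (is.null(cfg$schedule)) {
    cfg$schedule <- "occupational_human"
    defaulted <- c(defaulted, "schedule")
  }
  if (is.character(cfg$schedule)) {
    lib <- canned_schedules()
    if (!cfg$schedule %in% names(lib))
      stop("config$schedule: unknown schedule '", cfg$schedule,
           "'; known: ", paste(names(lib), collapse = ", "))
    schedule <- lib[[cfg$schedule]]
  } else {
    check_keys(cfg$schedule, SCHEDULE_KEYS, "config$schedule")
    schedule <- do.call(exposure_schedule, cfg$schedule)
  }

  scen <- cfg$scenario
  if (is.null(scen) || identical(scen, "none")) scen <- NULL
  else if (is.character(scen)) {
    scen <- switch(scen,
                   hepatic_impaired = scenario_hepatic_impaired(),
                   aged = scenario_aged(),
                   stop("config$scenario: unknown scenario '", scen, "'"))
  } else stop("config$scenario must be a scenario name")

  solver <- cfg$solver
  if (!is.null(solver)) check_keys(solver, SOLVER_KEYS, "config$solver")
  solver <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10,
                                   dt_out = NULL, method = "compiled"),
                              as.list(solver))

  mc <- cfg$monte_carlo
  if (!is.null(mc)) {
    check_keys(mc, MC_KEYS, "config$monte_carlo")
    if (is.null(cfg$seed))
      stop("config$seed is required for stochastic (monte_carlo) runs")
    mc <- utils::modifyList(list(n = 500,
                                 air_levels = default_air_grid(6),
                                 duration_days = 365), as.list(mc))
  }

  if (!is.null(cfg$overrides)) {
    ov <- unlist(cfg$overrides)
    bad <- names(ov)[!vapply(names(ov), valid_param_path, logical(1))]
    if (length(bad))
      stop("config$overrides: unknown parameter path(s): ",
           paste(bad, collapse = ", "))
    cfg$overrides <- ov
  }

  structure(list(species = cfg$species, overrides = cfg$overrides,
                 schedule = schedule, scenario = scen,
                 out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
                 seed = cfg$seed, solver = solver, monte_carlo = mc,
                 defaulted = defaulted),
            class = "mn_runconfig")
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  invisible(TRUE)
}

#' Resolve the parameter set of a run configuration
#'
#' Loads the species defaults, applies multiplicative overrides and the
#' scenario, in that order.
#'
#' @param cfg an `mn_runconfig`.
#' @return an `mn_species` parameter set.
#' @export
resolve_config_params <- function(cfg) {
  stopifnot(inherits(cfg, "mn_runconfig"))
  params <- load_species_defaults(cfg$species)
  if (length(cfg$overrides))
    params <- apply_scenario(params,
                             scenario("overrides", cfg$overrides))
  if (!is.null(cfg$scenario))
    params <- apply_scenario(params, cfg$scenario)
  params
}

#' Emit a resolved run configuration as YAML
#'
#' The emitted text re-parses to an identical configuration.
#'
#' @param cfg an `mn_runconfig`.
#' @return YAML string.
#' @export
format_config <- function(cfg) {
  stopifnot(inherits(cfg, "mn_runconfig"))
  sch <- cfg$schedule[c("air_conc", "hours_per_day", "days_per_week",
                        "duration_days", "start_time")]
  if (!is.null(cfg$schedule$diet_mg_per_day))
    sch$diet_mg_per_day <- cfg$schedule$diet_mg_per_day
  out <- list(species = cfg$species,
              schedule = sch,
              scenario = if (is.null(cfg$scenario)) "none"
                         else cfg$scenario$name,
              out_dir = cfg$out_dir,
              solver = cfg$solver[!vapply(cfg$solver, is.null,
                                          logical(1))])
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  if (length(cfg$overrides)) out$overrides <- as.list(cfg$overrides)
  if (!is.null(cfg$monte_carlo)) out$monte_carlo <- cfg$monte_carlo
  yaml::as.yaml(out, precision = 12)
}

run_metadata <- function(cfg) {
  list(package_version = as.character(utils::packageVersion("mnpbpk")),
       config_hash = substr(digest_string(format_config(cfg)), 1, 16),
       seed = cfg$seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# content hash without extra dependencies: md5 of the serialized text
digest_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
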