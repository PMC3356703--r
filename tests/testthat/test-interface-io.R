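# Configuration parsing, serialization round-trips and the CLI.

test_that("minimal configs resolve defaults; bad keys are rejected", {
  cfg <- parse_config("species: human\nschedule: occupational_human")
  expect_s3_class(cfg, "mn_runconfig")
  expect_equal(cfg$schedule$hours_per_day, 8)
  expect_equal(cfg$solver$rtol, 1e-8)
  expect_error(parse_config("species: human\nbogus_key: 1"),
               "config: unknown key")
  expect_error(parse_config("species: human\nsolver:\n  rtoll: 1"),
               "config\\$solver")
  expect_error(parse_config(
    "species: human\nschedule:\n  air_conc: 0.1\n  hours_per_day: 25\n  days_per_week: 5\n  duration_days: 10"),
    "hours_per_day")
  expect_error(parse_config("species: human\nmonte_carlo:\n  n: 10"),
               "seed")
  expect_error(parse_config("species: badger"), "unknown species")
  expect_error(parse_config(
    "species: human\noverrides:\n  no.such.path: 2"), "path")
})

test_that("resolved configs round-trip through YAML emission", {
  txt <- paste("species: monkey", "schedule: dorman_65day",
               "scenario: aged", "seed: 12",
               "overrides:", "  q_p: 0.9", sep = "\n")
  cfg <- parse_config(txt)
  cfg2 <- parse_config(format_config(cfg))
  expect_equal(cfg2$species, cfg$species)
  expect_equal(cfg2$schedule[names(cfg2$schedule) != "diet_ug_h"],
               cfg$schedule[names(cfg$schedule) != "diet_ug_h"])
  expect_equal(cfg2$scenario$name, cfg$scenario$name)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$overrides, cfg$overrides)
})

test_that("config overrides and scenarios reach the parameter set", {
  cfg <- parse_config(paste("species: rat", "scenario: aged",
                            "overrides:", "  bile.k_bile_c: 2",
                            sep = "\n"))
  p <- resolve_config_params(cfg)
  base <- cached_species("rat")
  expect_equal(p$bile$k_bile_c, base$bile$k_bile_c * 2)
  expect_equal(p$model$q_p, base$model$q_p * 0.75)
})

test_that("CLI simulate writes a well-formed time-course CSV", {
  out <- withr::local_tempdir()
  cfgfile <- file.path(out, "run.yaml")
  writeLines(paste("species: rat",
                   "schedule:",
                   "  air_conc: 0.5",
                   "  hours_per_day: 6",
                   "  days_per_week: 5",
                   "  duration_days: 2", sep = "\n"), cfgfile)
  status <- run_cli(c("simulate", "--config", cfgfile, "--out", out))
  expect_equal(status, 0L)
  csv <- utils::read.csv(file.path(out, "timecourse.csv"))
  expect_named(csv, c("time_h", "compartment", "free_ug", "bound_ug",
                      "conc_ug_per_g", "exposure_on"))
  expect_true("striatum" %in% csv$compartment)
  expect_true(file.exists(file.path(out, "run_info.json")))
})

test_that("CLI montecarlo is byte-reproducible for a fixed seed", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfgfile <- file.path(out1, "mc.yaml")
  writeLines(paste("species: human",
                   "seed: 7",
                   "monte_carlo:",
                   "  n: 3",
                   "  air_levels: [0.0, 0.1]",
                   "  duration_days: 30", sep = "\n"), cfgfile)
  expect_equal(run_cli(c("montecarlo", "--config", cfgfile,
                         "--out", out1)), 0L)
  expect_equal(run_cli(c("montecarlo", "--config", cfgfile,
                         "--out", out2)), 0L)
  f1 <- readLines(file.path(out1, "population_summary.csv"))
  f2 <- readLines(file.path(out2, "population_summary.csv"))
  expect_identical(f1, f2)
})

test_that("CLI scenario emits a CSAF row; usage errors exit nonzero", {
  out <- withr::local_tempdir()
  cfgfile <- file.path(out, "scn.yaml")
  writeLines(paste("species: rat",
                   "scenario: aged",
                   "schedule:",
                   "  air_conc: 0.5",
                   "  hours_per_day: 6",
                   "  days_per_week: 7",
                   "  duration_days: 5", sep = "\n"), cfgfile)
  expect_equal(run_cli(c("scenario", "--config", cfgfile, "--out", out)),
               0L)
  m <- utils::read.csv(file.path(out, "metrics.csv"))
  expect_true("csaf_end_of_exposure" %in% m$metric)
  csaf <- as.numeric(m$value[m$metric == "csaf_end_of_exposure"])
  expect_lt(csaf, 1)  # aged scenario
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(run_cli(c("simulate"))), 2L)
})
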