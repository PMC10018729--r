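write_config <- function(dir, ...) {
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(...), path)
  path
}

simulate_campaign <- function(root, seed = 1) {
  cfg_path <- write_config(root, seed = seed, scenario = list(
    library = list(n_compounds = 60),
    snow = list(n_road_sites = 6, n_background_sites = 2),
    wwtp = list(n_runoff = 5, n_diluted = 8, n_mixed = 7)
  ))
  config <- read_run_config(cfg_path)
  files <- run_simulate(config, file.path(root, "sim"))
  list(config = config, files = files, root = root)
}

test_that("simulate writes a loadable, reproducible campaign with a sidecar", {
  root <- withr::local_tempdir()
  sim <- simulate_campaign(root)
  expect_true(all(file.exists(sim$files)))
  # echoed config and a log accompany the outputs
  expect_true(file.exists(file.path(root, "sim", "config_echo.yaml")))
  expect_true(file.exists(file.path(root, "sim", "run.log")))

  # generated files load cleanly through the package readers
  tbl <- read_concentration_table(sim$files[["snow_concentrations"]])
  expect_gt(nrow(tbl), 0)
  lib <- read_compound_library(sim$files[["compound_library"]])
  expect_equal(nrow(lib), 60)
  eff <- read_effect_records(sim$files[["effect_records"]])
  expect_gt(nrow(eff), 0)
  meta <- read_sample_meta(sim$files[["sample_meta"]])
  expect_equal(nrow(meta), 8)

  # same config and seed reproduce every file byte-identically
  sim2_dir <- file.path(root, "sim2")
  run_simulate(sim$config, sim2_dir)
  for (f in names(sim$files)) {
    expect_identical(readLines(sim$files[[f]]),
                     readLines(file.path(sim2_dir, basename(sim$files[[f]]))),
                     label = f)
  }

  # ground truth lives only in the sidecar, not in the data files
  expect_false(any(grepl("true|dominant",
                         readLines(sim$files[["snow_concentrations"]], n = 1))))

  # missing scenario section is a config error naming the key
  bare <- read_run_config(write_config(root, seed = 1))
  expect_error(run_simulate(bare, file.path(root, "x")), "scenario",
               class = "meltrisk_config_error")
})

test_that("the risk command recovers planted drivers and reports provenance", {
  root <- withr::local_tempdir()
  sim <- simulate_campaign(root, seed = 3)
  config <- sim$config
  config$inputs <- list(
    snow_concentrations = sim$files[["snow_concentrations"]],
    compound_library = sim$files[["compound_library"]],
    effect_records = sim$files[["effect_records"]]
  )
  out <- file.path(root, "risk")
  log <- capture.output(res <- run_risk(config, out), type = "message")
  expect_true(all(file.exists(file.path(out, c("risk_profiles.csv",
                                               "contributions.csv",
                                               "exclusions.csv")))))
  expect_true(any(grepl("provenance", log)))

  # the planted dominant driver tops the fish ranking at each road site
  truth <- readr::read_csv(sim$files[["ground_truth_snow"]], show_col_types = FALSE) |>
    dplyr::filter(record == "dominant_driver")
  top <- tidy(res, "contributions") |>
    dplyr::filter(bqe == "fish", rank == 1)
  joined <- dplyr::inner_join(truth, top, by = "sample_id",
                              suffix = c("_true", "_found"))
  expect_equal(joined$compound_id_found, joined$compound_id_true)

  # an empty concentration table yields empty outputs with a warning, no error
  empty_csv <- file.path(root, "empty.csv")
  writeLines("sample_id,compound_id,concentration_ng_L", empty_csv)
  config$inputs$snow_concentrations <- empty_csv
  expect_warning(run_risk(config, file.path(root, "risk_empty")), "empty")
  prof <- readr::read_csv(file.path(root, "risk_empty", "risk_profiles.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(prof), 0)

  # missing inputs are named
  config$inputs$snow_concentrations <- file.path(root, "nope.csv")
  expect_error(run_risk(config, out), "nope.csv", class = "meltrisk_input_error")
})

test_that("the wwtp command writes attribution, removal and a consistent summary", {
  root <- withr::local_tempdir()
  sim <- simulate_campaign(root, seed = 4)
  config <- sim$config
  config$inputs <- list(
    wwtp_series = sim$files[["wwtp_series"]],
    snow_concentrations = sim$files[["snow_concentrations"]]
  )
  out <- file.path(root, "wwtp")
  res <- run_wwtp(config, out)
  att <- readr::read_csv(file.path(out, "attribution.csv"), show_col_types = FALSE)
  summary_lines <- readLines(file.path(out, "summary.txt"))
  # summary class counts equal the attribution CSV tallies
  for (cls in unique(att$source_class)) {
    n <- sum(att$source_class == cls)
    expect_true(any(grepl(paste0(cls, ": ", n), summary_lines)), label = cls)
  }
  expect_true(file.exists(file.path(out, "removal.csv")))

  # effluent absent: attribution still runs, removal skipped with a warning
  series <- readr::read_csv(sim$files[["wwtp_series"]], show_col_types = FALSE)
  infl_only <- file.path(root, "influent_only.csv")
  readr::write_csv(dplyr::filter(series, stream == "influent"), infl_only)
  config$inputs$wwtp_series <- infl_only
  expect_warning(run_wwtp(config, file.path(root, "wwtp2")), "skipped")
  expect_true(file.exists(file.path(root, "wwtp2", "attribution.csv")))
  expect_false(file.exists(file.path(root, "wwtp2", "removal.csv")))
})

test_that("the report command combines risk and wwtp summaries", {
  root <- withr::local_tempdir()
  sim <- simulate_campaign(root, seed = 5)
  config <- sim$config
  config$inputs <- list(
    snow_concentrations = sim$files[["snow_concentrations"]],
    compound_library = sim$files[["compound_library"]],
    effect_records = sim$files[["effect_records"]],
    wwtp_series = sim$files[["wwtp_series"]]
  )
  path <- run_report(config, file.path(root, "report"))
  lines <- readLines(path)
  expect_true(any(grepl("Mixture risk", lines)))
  expect_true(any(grepl("influent compounds", lines)))
})

test_that("result objects expose tidy, glance and autoplot views", {
  gen <- generate_compound_library(n_compounds = 40, seed = 19)
  snow <- generate_snow_samples(snow_scenario(n_road_sites = 4, seed = 19),
                                gen$library, gen$effects)
  res <- assess_risk(snow$table, gen$library, effect_database(gen$effects))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 1)
  expect_s3_class(autoplot(res), "ggplot")

  ww <- generate_wwtp_series(
    wwtp_scenario(n_runoff = 5, n_diluted = 8, n_mixed = 7, seed = 19),
    gen$library
  )
  att <- attribute_sources(ww$influent)
  expect_equal(sum(glance(att)[c("runoff_dominated", "diluted_other_source",
                                 "mixed", "unclassifiable")]),
               nrow(tidy(att)))
  expect_s3_class(autoplot(att), "ggplot")
  rem <- estimate_removal(ww$influent, ww$effluent)
  expect_equal(glance(rem)$n_compounds, nrow(tidy(rem)))
  expect_s3_class(autoplot(rem), "ggplot")
  expect_output(print(res), "risk_assessment")
  expect_output(print(att), "source_attribution")
  expect_output(print(rem), "removal_result")
})
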