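# Run configuration and the pipeline entry points behind the command-line
# wrapper (inst/cli/meltrisk): simulate, risk, wwtp, report. Every run echoes
# its configuration and a log into the output directory, so a run is fully
# reproducible from what it leaves behind.

#' Read a run configuration
#'
#' Loads a YAML run configuration and fills in package defaults for anything
#' not set: risk thresholds, the packaged baseline model, solubility-cap
#' tolerance 0.5, source-attribution cutoff 0.5, and `min_tu` 0.01 for
#' naming risk drivers. The `inputs` section holds paths to the CSV inputs;
#' `scenario` holds `snow`/`wwtp` subsections with [snow_scenario()] and
#' [wwtp_scenario()] fields for simulation.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("Config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort_config("Config must be a YAML mapping.")
  cfg$inputs <- cfg$inputs %||% list()
  cfg$cap_tolerance <- cfg$cap_tolerance %||% 0.5
  cfg$source_cutoff <- cfg$source_cutoff %||% 0.5
  cfg$min_tu <- cfg$min_tu %||% 0.01
  cfg$seed <- cfg$seed %||% 1
  structure(cfg, class = c("run_config", "list"))
}

config_thresholds <- function(config) {
  th <- config$thresholds
  if (is.null(th)) return(risk_thresholds())
  risk_thresholds(
    chronic = unlist(th$chronic) %||% c(algae = 0.02, crustacean = 0.001, fish = 0.01),
    acute = unlist(th$acute) %||% c(algae = 1, crustacean = 1, fish = 1)
  )
}

config_model <- function(config) {
  if (!is.null(config$baseline_model)) {
    if (is.character(config$baseline_model)) {
      read_baseline_model(config$baseline_model)
    } else {
      baseline_model(config$baseline_model$slopes, config$baseline_model$intercepts)
    }
  } else {
    default_baseline_model()
  }
}

prepare_out_dir <- function(config, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory: ", out_dir),
                   class = c("meltrisk_io_error", "meltrisk_error"))
  }
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_echo.yaml"))
  invisible(out_dir)
}

log_lines <- function(out_dir, lines) {
  cat(paste0(lines, "\n"), file = file.path(out_dir, "run.log"), append = TRUE, sep = "")
  inform(lines)
}

need_input <- function(config, key) {
  path <- config$inputs[[key]]
  if (is.null(path)) abort_config(paste0("Config is missing inputs.", key, "."))
  if (!file.exists(path)) {
    abort_input(paste0("Input file for '", key, "' not found: ", path))
  }
  path
}

write_library_csv <- function(library, path) {
  out <- library
  out$uses <- purrr::map_chr(out$uses, paste, collapse = ";")
  readr::write_csv(out, path)
}

#' Simulate a full synthetic campaign
#'
#' Generates a compound library with effect data, snow-site concentrations
#' and a WWTP influent/effluent series, and writes them in the exact CSV
#' formats the analysis commands consume. Ground truth goes to separate
#' sidecar files (`ground_truth_*.csv`), never into the data files, so a
#' pipeline cannot accidentally read it.
#'
#' @param config A [read_run_config()] result with a `scenario` section
#'   (subsections `library`, `snow`, `wwtp`; missing fields take the
#'   scenario defaults).
#' @param out_dir Output directory.
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, the named character vector of files written.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (is.null(config$scenario)) abort_config("Config is missing the `scenario` section.")
  seed <- seed %||% config$seed
  config$seed <- seed
  prepare_out_dir(config, out_dir)
  lib_args <- config$scenario$library %||% list()
  lib_args$seed <- lib_args$seed %||% seed
  gen <- do.call(generate_compound_library, lib_args)
  snow_args <- config$scenario$snow %||% list()
  snow_args$seed <- snow_args$seed %||% seed
  snow <- generate_snow_samples(do.call(snow_scenario, snow_args),
                                gen$library, gen$effects)
  wwtp_args <- config$scenario$wwtp %||% list()
  wwtp_args$seed <- wwtp_args$seed %||% seed
  wwtp <- generate_wwtp_series(do.call(wwtp_scenario, wwtp_args), gen$library)

  files <- c(
    compound_library = file.path(out_dir, "compound_library.csv"),
    effect_records = file.path(out_dir, "effect_records.csv"),
    snow_concentrations = file.path(out_dir, "snow_concentrations.csv"),
    sample_meta = file.path(out_dir, "sample_meta.csv"),
    wwtp_series = file.path(out_dir, "wwtp_series.csv"),
    ground_truth_snow = file.path(out_dir, "ground_truth_snow.csv"),
    ground_truth_wwtp = file.path(out_dir, "ground_truth_wwtp.csv")
  )
  write_library_csv(gen$library, files[["compound_library"]])
  readr::write_csv(gen$effects, files[["effect_records"]])
  write_concentration_table(snow$table, files[["snow_concentrations"]])
  readr::write_csv(snow$meta, files[["sample_meta"]])
  readr::write_csv(
    bind_rows(
      snow$truth$category_sums |> mutate(record = "category_sum"),
      snow$truth$dominant |> mutate(record = "dominant_driver")
    ) |>
      select("record", dplyr::everything()),
    files[["ground_truth_snow"]]
  )
  wwtp_long <- bind_rows(wwtp$influent, wwtp$effluent) |>
    select("date", "stream", "flow_m3_day", "compound_id",
           "concentration_ng_L", "mdl_ng_L")
  readr::write_csv(wwtp_long, files[["wwtp_series"]])
  readr::write_csv(wwtp$truth, files[["ground_truth_wwtp"]])
  log_lines(out_dir, c(
    paste0("simulate: seed ", seed),
    paste0("simulate: ", nrow(gen$library), " compounds, ",
           nrow(snow$table), " snow entries, ",
           nrow(wwtp_long), " WWTP rows written")
  ))
  invisible(files)
}

#' Run the mixture risk assessment
#'
#' Reads the snow concentration table, compound library and experimental
#' effect records named in the config, applies MDL censoring, runs
#' [assess_risk()] and writes `risk_profiles.csv`, `contributions.csv` and
#' `exclusions.csv`. The log records how many compound-BQE effect values came
#' from each provenance class.
#'
#' @param config A [read_run_config()] result.
#' @param out_dir Output directory.
#' @return The [assess_risk()] object, invisibly.
#' @export
run_risk <- function(config, out_dir) {
  prepare_out_dir(config, out_dir)
  table <- read_concentration_table(need_input(config, "snow_concentrations"))
  library <- read_compound_library(need_input(config, "compound_library"))
  effects <- if (!is.null(config$inputs$effect_records)) {
    read_effect_records(need_input(config, "effect_records"))
  } else {
    NULL
  }
  db <- effect_database(effects, model = config_model(config),
                        cap_tolerance = config$cap_tolerance)
  if (nrow(table) > 0) {
    table <- censor_below_mdl(table, default_mdl = config$default_mdl)
  } else {
    warn("Concentration table is empty; writing empty risk outputs.")
  }
  res <- assess_risk(table, library, db, thresholds = config_thresholds(config))
  readr::write_csv(res$profiles, file.path(out_dir, "risk_profiles.csv"))
  readr::write_csv(res$contributions, file.path(out_dir, "contributions.csv"))
  readr::write_csv(res$exclusions, file.path(out_dir, "exclusions.csv"))
  prov <- count(res$effect_table, .data$provenance)
  log_lines(out_dir, c(
    paste0("risk: ", length(unique(res$profiles$sample_id)), " samples assessed"),
    paste0("risk: effect values by provenance: ",
           paste(prov$provenance, prov$n, sep = "=", collapse = ", ")),
    paste0("risk: ", nrow(res$exclusions), " compound x BQE pairs excluded")
  ))
  invisible(res)
}

#' Run the WWTP source-attribution and removal analysis
#'
#' Reads the long WWTP series (influent and effluent in one file with a
#' `stream` column), attributes influent compounds to sources by flow
#' correlation, and — when effluent data are present — estimates removal
#' rates over the configured date window for compounds also found in the
#' snow table (when one is configured). Writes `attribution.csv`,
#' `removal.csv` and a plain-text `summary.txt` with class and bin counts.
#'
#' @param config A [read_run_config()] result. Optional fields:
#'   `date_window` (two dates) and `inputs$snow_concentrations` (to restrict
#'   removal to compounds detected in snow).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `source_attribution` and (possibly
#'   `NULL`) `removal_result` objects.
#' @export
run_wwtp <- function(config, out_dir) {
  prepare_out_dir(config, out_dir)
  series <- readr::read_csv(need_input(config, "wwtp_series"), show_col_types = FALSE,
                            progress = FALSE)
  require_columns(series, c("date", "stream", "flow_m3_day", "compound_id",
                            "concentration_ng_L"), "WWTP series")
  if ("mdl_ng_L" %in% names(series)) {
    series <- censor_below_mdl(series, default_mdl = config$default_mdl)
  }
  influent <- series |> filter(.data$stream == "influent")
  effluent <- series |> filter(.data$stream == "effluent")
  if (nrow(influent) == 0) abort_input("WWTP series contains no influent rows.")
  att <- attribute_sources(influent, cutoff = config$source_cutoff)
  readr::write_csv(att$attribution, file.path(out_dir, "attribution.csv"))

  removal <- NULL
  if (nrow(effluent) == 0) {
    warn("No effluent rows; removal analysis skipped.")
    log_lines(out_dir, "wwtp: no effluent data, removal skipped")
  } else {
    snow_compounds <- NULL
    if (!is.null(config$inputs$snow_concentrations) &&
        file.exists(config$inputs$snow_concentrations)) {
      snow <- read_concentration_table(config$inputs$snow_concentrations)
      if ("mdl_ng_L" %in% names(snow) && any(is.finite(snow$mdl_ng_L))) {
        snow <- censor_below_mdl(snow, default_mdl = config$default_mdl)
      }
      snow_compounds <- unique(snow$compound_id[!snow$censored])
    }
    window <- if (!is.null(config$date_window)) as.Date(unlist(config$date_window)) else NULL
    removal <- estimate_removal(influent, effluent, compounds = snow_compounds,
                                window = window)
    readr::write_csv(removal$removal, file.path(out_dir, "removal.csv"))
  }

  class_counts <- count(att$attribution, .data$source_class)
  lines <- c(
    "WWTP source attribution and removal summary",
    paste0("influent compounds: ", nrow(att$attribution)),
    paste0("  ", class_counts$source_class, ": ", class_counts$n)
  )
  if (!is.null(removal)) {
    bin_counts <- count(removal$removal, .data$bin)
    lines <- c(lines,
               paste0("removal analysis compounds (snow x influent intersection): ",
                      removal$n_intersection),
               paste0("  ", bin_counts$bin, ": ", bin_counts$n))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  log_lines(out_dir, paste0("wwtp: ", nrow(att$attribution), " compounds attributed"))
  invisible(list(attribution = att, removal = removal))
}

#' Render a combined text report
#'
#' Runs the risk and WWTP analyses (whichever inputs are configured) and
#' writes a single human-readable `report.txt` with exceedance counts per
#' BQE, top risk drivers, source-class counts and removal-bin counts.
#'
#' @param config A [read_run_config()] result.
#' @param out_dir Output directory.
#' @return Invisibly, the path of the report.
#' @export
run_report <- function(config, out_dir) {
  prepare_out_dir(config, out_dir)
  lines <- "meltrisk combined report"
  if (!is.null(config$inputs$snow_concentrations)) {
    res <- run_risk(config, out_dir)
    exc <- res$profiles |>
      group_by(.data$bqe) |>
      summarise(chronic = sum(.data$chronic_exceeded),
                acute = sum(.data$acute_exceeded), .groups = "drop")
    lines <- c(lines, "", "Mixture risk (samples exceeding thresholds):",
               sprintf("  %-10s chronic %d / acute %d", exc$bqe, exc$chronic, exc$acute))
    top <- res$contributions |> filter(.data$rank == 1)
    if (nrow(top) > 0) {
      drivers <- top |> count(.data$compound_id, sort = TRUE) |> head(5)
      lines <- c(lines, "Most frequent top risk drivers:",
                 sprintf("  %s (top at %d sample x BQE)", drivers$compound_id, drivers$n))
    }
  }
  if (!is.null(config$inputs$wwtp_series)) {
    ww <- run_wwtp(config, out_dir)
    lines <- c(lines, "", readLines(file.path(out_dir, "summary.txt")))
  }
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  log_lines(out_dir, "report: written")
  invisible(path)
}
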