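# EC50 selection: experimental 5th percentile per BQE, else baseline-toxicity
# QSAR prediction from log Kow, capped at aqueous solubility.

#' 5th percentile of experimental EC50 values
#'
#' Aggregates the experimental acute EC50 values available for one compound
#' and one biological quality element into a single, conservative value: the
#' 5th percentile across all supplied records (species duplicates included),
#' with linear interpolation between the closest order statistics (the common
#' "type 7" convention; configurable for sensitivity analysis).
#'
#' @param values Numeric vector of positive EC50 values, mg/L.
#' @param prob Percentile as a probability; default 0.05.
#' @param type Quantile type passed to [stats::quantile()]; default 7.
#' @return The percentile in mg/L. A single value is returned unchanged.
#' @export
#' @examples
#' percentile5_ec50(c(0.5, 1.2, 8, 40))
percentile5_ec50 <- function(values, prob = 0.05, type = 7) {
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values))) {
    abort("No experimental EC50 values supplied.",
          class = c("meltrisk_no_data", "meltrisk_error"))
  }
  if (anyNA(values)) abort_validation("EC50 values must not contain NA.")
  if (any(values <= 0)) abort_validation("EC50 values must be strictly positive.")
  unname(quantile(values, probs = prob, type = type, names = FALSE))
}

#' Baseline-toxicity (narcosis) QSAR model
#'
#' A minimal per-BQE linear model on the log scale,
#' `log10 EC50 [mg/L] = a * logKow + b`, representing baseline (narcotic)
#' toxicity. Coefficients are data, not code: the packaged defaults
#' (`default_baseline_model()`, read from a shipped YAML file) are generic
#' narcosis-style values intended as a documented starting point; analyses of
#' real data should supply coefficients fitted for their compound domain.
#'
#' @param slopes,intercepts Named numeric vectors with entries `algae`,
#'   `crustacean`, `fish`.
#' @return An object of class `baseline_model`.
#' @export
baseline_model <- function(slopes, intercepts) {
  slopes <- unlist(slopes)
  intercepts <- unlist(intercepts)
  for (nm in list(slopes, intercepts)) {
    missing <- setdiff(BQE_LEVELS, names(nm))
    if (length(missing) > 0) {
      abort_config(paste0("Baseline model must define coefficients for all BQEs; missing: ",
                          paste(missing, collapse = ", ")))
    }
  }
  structure(list(slopes = slopes[BQE_LEVELS], intercepts = intercepts[BQE_LEVELS]),
            class = "baseline_model")
}

#' @rdname baseline_model
#' @param path YAML file with keys `slopes`, `intercepts` (each mapping BQE to
#'   a number) and optionally `cap_tolerance`.
#' @export
read_baseline_model <- function(path) {
  if (!file.exists(path)) abort_input(paste0("Baseline model file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$slopes) || is.null(cfg$intercepts)) {
    abort_config(paste0("Baseline model file '", path, "' must contain `slopes` and `intercepts`."))
  }
  baseline_model(cfg$slopes, cfg$intercepts)
}

#' @rdname baseline_model
#' @export
default_baseline_model <- function() {
  read_baseline_model(system.file("extdata", "baseline_model.yaml",
                                  package = "meltrisk", mustWork = TRUE))
}

#' Predict an EC50 from log Kow with the baseline model
#'
#' @param log_kow Numeric vector of log10 octanol-water partition
#'   coefficients.
#' @param bqe A single BQE label (synonyms such as `"daphnia"` accepted).
#' @param model A [baseline_model()].
#' @return Predicted EC50 in mg/L, strictly positive; `NA` where `log_kow` is
#'   `NA` (the compound is then excluded from that BQE with a warning
#'   downstream, never imputed).
#' @export
predict_baseline_ec50 <- function(log_kow, bqe, model) {
  if (!inherits(model, "baseline_model")) abort_config("`model` must be a baseline_model.")
  bqe <- normalize_bqe(bqe)
  stopifnot(length(bqe) == 1)
  10^(model$slopes[[bqe]] * log_kow + model$intercepts[[bqe]])
}

#' Cap a predicted EC50 at the compound's water solubility
#'
#' An effect concentration cannot exceed the aqueous solubility: where a
#' predicted EC50 lies more than `tolerance` log10 units above the solubility,
#' it is replaced by the solubility and marked `solubility_capped`. The
#' half-log tolerance absorbs uncertainty in the solubility estimate. Capping
#' is contractive (never increases the EC50), so toxic units never decrease —
#' the conservative direction.
#'
#' @param ec50_pred Predicted EC50, mg/L, > 0.
#' @param log10_solubility log10 of aqueous solubility in mg/L; `NA` means
#'   unknown (no cap applied, with a warning).
#' @param tolerance Tolerance in log10 units; default 0.5.
#' @return A list with `ec50_mg_L` and `provenance` (`"predicted"` or
#'   `"solubility_capped"`).
#' @export
apply_solubility_cap <- function(ec50_pred, log10_solubility, tolerance = 0.5) {
  if (!is.finite(ec50_pred) || ec50_pred <= 0) {
    abort_validation("`ec50_pred` must be a positive number.")
  }
  if (!is.finite(log10_solubility)) {
    warn("Solubility unknown; predicted EC50 left uncapped.")
    return(list(ec50_mg_L = ec50_pred, provenance = "predicted"))
  }
  if (log10(ec50_pred) - log10_solubility > tolerance) {
    list(ec50_mg_L = 10^log10_solubility, provenance = "solubility_capped")
  } else {
    list(ec50_mg_L = ec50_pred, provenance = "predicted")
  }
}

#' Read experimental effect records
#'
#' @param path CSV with columns `compound_id`, `bqe`, `ec50_mg_L` and
#'   optionally `species`, `reference`. BQE synonyms (e.g. `daphnia`) are
#'   normalised.
#' @return A tibble of experimental effect records.
#' @export
read_effect_records <- function(path) {
  if (!file.exists(path)) abort_input(paste0("Effect record file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c("compound_id", "bqe", "ec50_mg_L"),
                  paste0("Effect record file '", path, "'"))
  out <- tibble(
    compound_id = as.character(raw$compound_id),
    bqe = normalize_bqe(raw$bqe),
    ec50_mg_L = suppressWarnings(as.numeric(raw$ec50_mg_L)),
    species = if ("species" %in% names(raw)) as.character(raw$species) else NA_character_,
    reference = if ("reference" %in% names(raw)) as.character(raw$reference) else NA_character_
  )
  if (any(!is.finite(out$ec50_mg_L) | out$ec50_mg_L <= 0)) {
    abort_validation(paste0("Non-positive or unparseable ec50_mg_L in '", path, "'."))
  }
  out
}

#' Build an effect database
#'
#' Bundles the experimental effect records, the baseline QSAR model and the
#' solubility-cap tolerance into the lookup object used by [select_ec50()].
#' Lookup is deterministic: the same inputs always yield the same EC50 and
#' provenance.
#'
#' @param experimental Tibble of experimental records (as from
#'   [read_effect_records()]); may be empty.
#' @param model A [baseline_model()]; default the packaged one.
#' @param cap_tolerance Solubility-cap tolerance in log10 units; default 0.5.
#' @param percentile_prob,percentile_type Convention for the experimental
#'   percentile; see [percentile5_ec50()].
#' @return An object of class `effect_database`.
#' @export
effect_database <- function(experimental = NULL,
                            model = default_baseline_model(),
                            cap_tolerance = 0.5,
                            percentile_prob = 0.05,
                            percentile_type = 7) {
  if (is.null(experimental)) {
    experimental <- tibble(compound_id = character(0), bqe = character(0),
                           ec50_mg_L = numeric(0), species = character(0),
                           reference = character(0))
  }
  require_columns(experimental, c("compound_id", "bqe", "ec50_mg_L"), "Experimental records")
  experimental$bqe <- normalize_bqe(experimental$bqe)
  structure(
    list(experimental = experimental, model = model, cap_tolerance = cap_tolerance,
         percentile_prob = percentile_prob, percentile_type = percentile_type),
    class = "effect_database"
  )
}

#' Select the EC50 for one compound and BQE
#'
#' Applies the selection hierarchy: (1) if experimental records exist for the
#' compound and BQE, their 5th percentile with provenance `experimental`
#' (prediction is never consulted); else (2) the baseline-QSAR prediction from
#' log Kow, solubility-capped; else (3) no effect value — the compound is
#' excluded from that BQE and reported, never imputed.
#'
#' @param compound One-row tibble (or list) with `compound_id` and optionally
#'   `log_kow`, `log10_solubility_mg_L`.
#' @param bqe BQE label.
#' @param db An [effect_database()].
#' @return A one-row tibble `compound_id`, `bqe`, `ec50_mg_L`, `provenance`,
#'   or `NULL` (with condition class `meltrisk_no_effect_value` signalled as a
#'   warning) when no value can be derived.
#' @export
select_ec50 <- function(compound, bqe, db) {
  if (!inherits(db, "effect_database")) abort_config("`db` must be an effect_database.")
  bqe <- normalize_bqe(bqe)
  cid <- compound$compound_id
  exp_vals <- db$experimental$ec50_mg_L[db$experimental$compound_id == cid &
                                          db$experimental$bqe == bqe]
  if (length(exp_vals) > 0) {
    return(tibble(
      compound_id = cid, bqe = bqe,
      ec50_mg_L = percentile5_ec50(exp_vals, prob = db$percentile_prob,
                                   type = db$percentile_type),
      provenance = "experimental"
    ))
  }
  log_kow <- compound$log_kow %||% NA_real_
  if (!is.finite(log_kow)) {
    warn(paste0("No experimental EC50 and no log Kow for '", cid, "' (", bqe,
                "); compound excluded from this BQE."),
         class = "meltrisk_no_effect_value")
    return(NULL)
  }
  pred <- predict_baseline_ec50(log_kow, bqe, db$model)
  sol <- compound$log10_solubility_mg_L %||% NA_real_
  capped <- if (is.finite(sol)) {
    apply_solubility_cap(pred, sol, db$cap_tolerance)
  } else {
    list(ec50_mg_L = pred, provenance = "predicted")
  }
  tibble(compound_id = cid, bqe = bqe,
         ec50_mg_L = capped$ec50_mg_L, provenance = capped$provenance)
}

#' Derive the full effect table for a compound library
#'
#' Runs [select_ec50()] for every compound and BQE and collects the
#' exclusions (no experimental data and no log Kow) into a report attached as
#' attribute `"exclusions"`.
#'
#' @param library Compound library tibble.
#' @param db An [effect_database()].
#' @param bqes BQEs to cover; default all three.
#' @return Tibble `compound_id`, `bqe`, `ec50_mg_L`, `provenance`; attribute
#'   `exclusions` is a tibble `compound_id`, `bqe`, `reason`.
#' @export
build_effect_table <- function(library, db, bqes = BQE_LEVELS) {
  require_columns(library, "compound_id", "Compound library")
  bqes <- normalize_bqe(bqes)
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(library))) {
    comp <- library[i, ]
    for (b in bqes) {
      rec <- withCallingHandlers(
        select_ec50(comp, b, db),
        meltrisk_no_effect_value = function(w) invokeRestart("muffleWarning")
      )
      if (is.null(rec)) {
        excl[[length(excl) + 1]] <- tibble(
          compound_id = comp$compound_id, bqe = b,
          reason = "no experimental EC50 and no log_kow"
        )
      } else {
        rows[[length(rows) + 1]] <- rec
      }
    }
  }
  out <- if (length(rows) > 0) bind_rows(rows) else {
    tibble(compound_id = character(0), bqe = character(0),
           ec50_mg_L = numeric(0), provenance = character(0))
  }
  attr(out, "exclusions") <- if (length(excl) > 0) bind_rows(excl) else {
    tibble(compound_id = character(0), bqe = character(0), reason = character(0))
  }
  out
}
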