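# WWTP source attribution by flow correlation and removal-rate estimation
# from cumulative influent/effluent loads.

SOURCE_CLASSES <- c("runoff_dominated", "diluted_other_source", "mixed", "unclassifiable")
REMOVAL_BINS <- c("effluent_below_mdl", "high", "medium", "low", "negative")

# Long WWTP series: one row per (date, compound). Checks dates/flows and
# returns the tibble with a censored column present.
validate_wwtp_series <- function(series, what = "WWTP series") {
  require_columns(series, c("date", "flow_m3_day", "compound_id", "concentration_ng_L"),
                  what)
  series$date <- as.Date(series$date)
  if (!"censored" %in% names(series)) series$censored <- FALSE
  if (any(!is.finite(series$flow_m3_day) | series$flow_m3_day <= 0)) {
    abort_validation(paste0(what, ": flows must be positive."))
  }
  flows <- distinct(series, .data$date, .data$flow_m3_day)
  if (anyDuplicated(flows$date)) {
    abort_validation(paste0(what, ": conflicting flows for a single date."))
  }
  series
}

#' Spearman correlation between a compound's concentrations and inlet flow
#'
#' Rank-correlates the daily influent concentrations of one compound with the
#' daily inlet flow (average ranks for ties). Concentrations rise with flow
#' only for compounds that actually travel with the runoff, while runoff
#' dilutes compounds from other, steadier sources — so the sign and strength
#' of the coefficient carry the source information.
#'
#' Only detected (non-censored) days enter; fewer than 3 paired observations
#' is an insufficient-data condition and the compound is reported
#' unclassifiable.
#'
#' @param series Influent series tibble: `date`, `flow_m3_day`,
#'   `compound_id`, `concentration_ng_L`, optional `censored`.
#' @param compound_id Compound to correlate.
#' @return A list with `rho` (in `[-1, 1]`, `NA` when insufficient) and `n`
#'   (paired observations used).
#' @export
spearman_flow_correlation <- function(series, compound_id) {
  series <- validate_wwtp_series(series)
  rows <- series[series$compound_id == compound_id & !series$censored, , drop = FALSE]
  n <- nrow(rows)
  if (n < 3) {
    warn(paste0("Only ", n, " detected observation(s) for '", compound_id,
                "'; need >= 3 for a correlation."),
         class = "meltrisk_insufficient_data")
    return(list(rho = NA_real_, n = n))
  }
  list(rho = cor(rows$concentration_ng_L, rows$flow_m3_day, method = "spearman"), n = n)
}

#' Classify a compound's dominant source from its flow correlation
#'
#' @param rho Spearman coefficient(s) in `[-1, 1]`; `NA` maps to
#'   `"unclassifiable"`.
#' @param cutoff Absolute-value cutoff; default 0.5. Strict: `rho` exactly at
#'   the cutoff is `"mixed"`.
#' @return Character vector: `rho > cutoff` is `"runoff_dominated"`,
#'   `rho < -cutoff` is `"diluted_other_source"`, otherwise `"mixed"`
#'   (more complex discharge patterns from several sources).
#' @export
classify_source <- function(rho, cutoff = 0.5) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE)) {
    abort_validation("`rho` must lie in [-1, 1].")
  }
  dplyr::case_when(
    is.na(rho) ~ "unclassifiable",
    rho > cutoff ~ "runoff_dominated",
    rho < -cutoff ~ "diluted_other_source",
    TRUE ~ "mixed"
  )
}

#' Attribute influent compounds to sources by flow correlation
#'
#' Runs [spearman_flow_correlation()] and [classify_source()] for every
#' compound in an influent series.
#'
#' @param series Influent series tibble.
#' @param cutoff Classification cutoff on `|rho|`; default 0.5.
#' @return An object of class `source_attribution` wrapping a tibble
#'   `compound_id`, `rho`, `n`, `source_class`; has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
attribute_sources <- function(series, cutoff = 0.5) {
  series <- validate_wwtp_series(series, "Influent series")
  compounds <- sort(unique(series$compound_id))
  rows <- purrr::map(compounds, function(cid) {
    res <- withCallingHandlers(
      spearman_flow_correlation(series, cid),
      meltrisk_insufficient_data = function(w) invokeRestart("muffleWarning")
    )
    tibble(compound_id = cid, rho = res$rho, n = res$n)
  })
  out <- bind_rows(rows) |> mutate(source_class = classify_source(.data$rho, cutoff))
  structure(list(attribution = out, cutoff = cutoff), class = "source_attribution")
}

#' Cumulative load of each compound over the analysis period
#'
#' Load on day d is concentration (ng/L) times flow (m3/day); with 1000 L per
#' m3 this is micrograms per day, so the cumulative load is reported in
#' micrograms over the period. Censored days contribute zero by default.
#'
#' @param series WWTP series tibble (influent or effluent).
#' @param window Optional length-2 Date vector restricting the period
#'   (inclusive).
#' @param censored_as `"zero"` (default) or `"half_mdl"` (requires an
#'   `mdl_ng_L` column) for sensitivity analysis.
#' @return Tibble `compound_id`, `load_ug`, `n_days`, `all_censored`.
#' @export
cumulative_load <- function(series, window = NULL, censored_as = c("zero", "half_mdl")) {
  censored_as <- match.arg(censored_as)
  series <- validate_wwtp_series(series)
  if (!is.null(window)) {
    window <- as.Date(window)
    series <- series[series$date >= min(window) & series$date <= max(window), , drop = FALSE]
  }
  if (nrow(series) == 0) {
    return(tibble(compound_id = character(0), load_ug = numeric(0),
                  n_days = integer(0), all_censored = logical(0)))
  }
  series$.value <- effective_concentration(series, censored_as)
  series |>
    group_by(.data$compound_id) |>
    summarise(
      load_ug = kahan_sum(.data$.value * .data$flow_m3_day),
      n_days = n(),
      all_censored = all(.data$censored),
      .groups = "drop"
    )
}

bin_removal <- function(rate, effluent_all_censored) {
  dplyr::case_when(
    effluent_all_censored ~ "effluent_below_mdl",
    rate > 0.8 ~ "high",
    rate >= 0.5 ~ "medium",
    rate >= 0 ~ "low",
    TRUE ~ "negative"
  )
}

#' Removal rate from cumulative loads
#'
#' `removal_rate = 1 - effluent_load / influent_load`, possibly negative when
#' the effluent load exceeds the influent load (e.g. in-plant deconjugation
#' or matrix effects), and never above 1. Bins: effluent entirely below the
#' MDL is its own class; then high (> 80%), medium (50-80%, both ends
#' inclusive), low (>= 0 and < 50%), negative (< 0).
#'
#' @param influent_load,effluent_load Cumulative loads over the same period,
#'   same units; `influent_load` must be positive (an undefined removal is an
#'   error condition, reported and excluded from binning upstream).
#' @param effluent_all_censored Logical: every effluent day below the MDL.
#' @return A list with `removal_rate` (fraction) and `bin`.
#' @export
#' @examples
#' removal_rate(100, 1) # 99% removal, bin "high"
removal_rate <- function(influent_load, effluent_load, effluent_all_censored = FALSE) {
  if (!is.finite(influent_load) || influent_load <= 0) {
    abort(paste0("Removal undefined: influent load must be positive (got ",
                 influent_load, ")."),
          class = c("meltrisk_undefined_removal", "meltrisk_error"))
  }
  if (!is.finite(effluent_load) || effluent_load < 0) {
    abort_validation("Effluent load must be non-negative.")
  }
  rate <- 1 - effluent_load / influent_load
  list(removal_rate = rate, bin = bin_removal(rate, effluent_all_censored))
}

#' Estimate per-compound removal rates from influent and effluent series
#'
#' Computes cumulative loads for both streams over the common date window and
#' derives removal rates and bins. The compound set is the intersection of
#' the influent compounds with `compounds` (typically the compounds detected
#' in snow, so the analysis covers compounds found both in snow and in the
#' influent). Mismatched date spans are truncated to the overlap with a
#' warning; non-overlapping spans are an error.
#'
#' @param influent,effluent WWTP series tibbles.
#' @param compounds Optional character vector to intersect the influent
#'   compound set with (e.g. compounds detected in snow samples).
#' @param window Optional explicit length-2 Date window.
#' @param censored_as Treatment of censored days, see [cumulative_load()].
#' @return An object of class `removal_result` wrapping a tibble
#'   `compound_id`, `influent_load_ug`, `effluent_load_ug`, `removal_rate`,
#'   `bin`, plus `undefined` (compounds with zero influent load, excluded
#'   from binning) and the intersection size; has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
estimate_removal <- function(influent, effluent, compounds = NULL, window = NULL,
                             censored_as = c("zero", "half_mdl")) {
  censored_as <- match.arg(censored_as)
  influent <- validate_wwtp_series(influent, "Influent series")
  effluent <- validate_wwtp_series(effluent, "Effluent series")
  span_in <- range(influent$date)
  span_ef <- range(effluent$date)
  overlap <- c(max(span_in[1], span_ef[1]), min(span_in[2], span_ef[2]))
  if (overlap[1] > overlap[2]) {
    abort_input("Influent and effluent date spans do not overlap.")
  }
  if (!identical(span_in, span_ef)) {
    warn(paste0("Influent and effluent spans differ; truncated to overlap ",
                overlap[1], " to ", overlap[2], "."))
  }
  if (is.null(window)) window <- overlap
  pool <- unique(influent$compound_id)
  if (!is.null(compounds)) pool <- intersect(pool, compounds)
  influent <- influent[influent$compound_id %in% pool, , drop = FALSE]
  effluent <- effluent[effluent$compound_id %in% pool, , drop = FALSE]
  loads_in <- cumulative_load(influent, window = window, censored_as = censored_as)
  loads_ef <- cumulative_load(effluent, window = window, censored_as = censored_as)
  joined <- loads_in |>
    rename(influent_load_ug = "load_ug", influent_all_censored = "all_censored") |>
    left_join(loads_ef |>
                rename(effluent_load_ug = "load_ug",
                       effluent_all_censored = "all_censored") |>
                select("compound_id", "effluent_load_ug", "effluent_all_censored"),
              by = "compound_id") |>
    mutate(
      effluent_load_ug = dplyr::coalesce(.data$effluent_load_ug, 0),
      effluent_all_censored = dplyr::coalesce(.data$effluent_all_censored, TRUE)
    )
  undefined <- joined |> filter(.data$influent_load_ug <= 0)
  if (nrow(undefined) > 0) {
    warn(paste0(nrow(undefined), " compound(s) had zero influent load over the ",
                "window; removal undefined, excluded from binning."))
  }
  removal <- joined |>
    filter(.data$influent_load_ug > 0) |>
    mutate(
      removal_rate = 1 - .data$effluent_load_ug / .data$influent_load_ug,
      bin = bin_removal(.data$removal_rate, .data$effluent_all_censored)
    ) |>
    select("compound_id", "influent_load_ug", "effluent_load_ug",
           "removal_rate", "bin") |>
    arrange(desc(.data$removal_rate))
  structure(
    list(removal = removal, undefined = undefined$compound_id,
         n_intersection = length(pool), window = as.Date(window)),
    class = "removal_result"
  )
}

#' @export
print.source_attribution <- function(x, ...) {
  cat("<source_attribution> cutoff |rho| >", x$cutoff, "\n")
  print(count(x$attribution, .data$source_class))
  invisible(x)
}

#' @export
print.removal_result <- function(x, ...) {
  cat("<removal_result>", x$n_intersection, "compounds, window",
      format(x$window[1]), "to", format(x$window[2]), "\n")
  print(count(x$removal, .data$bin))
  invisible(x)
}
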