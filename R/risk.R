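# Toxic units, mixture sums under concentration addition, threshold
# classification and risk-driver ranking.

#' Risk thresholds per biological quality element
#'
#' Chronic TUsum thresholds default to the values commonly used for
#' prioritising mixture risks: algae 0.02, crustaceans (daphnia) 0.001,
#' fish 0.01. The acute threshold defaults to TUsum = 1 for every BQE (a
#' mixture at its median acute effect level) and is configurable. Exceedance
#' is strict: a TUsum exactly at a threshold does not exceed it.
#'
#' @param chronic,acute Named numeric vectors over `algae`, `crustacean`,
#'   `fish`; all positive, with `acute >= chronic` per BQE.
#' @return An object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(chronic = c(algae = 0.02, crustacean = 0.001, fish = 0.01),
                            acute = c(algae = 1, crustacean = 1, fish = 1)) {
  chronic <- unlist(chronic)
  acute <- unlist(acute)
  names(chronic) <- normalize_bqe(names(chronic))
  names(acute) <- normalize_bqe(names(acute))
  for (nm in list(chronic, acute)) {
    if (length(setdiff(BQE_LEVELS, names(nm))) > 0) {
      abort_config("Thresholds must be defined for algae, crustacean and fish.")
    }
  }
  chronic <- chronic[BQE_LEVELS]
  acute <- acute[BQE_LEVELS]
  if (any(chronic <= 0) || any(acute <= 0)) abort_config("Thresholds must be positive.")
  if (any(acute < chronic)) abort_config("Acute thresholds must be >= chronic thresholds.")
  structure(list(chronic = chronic, acute = acute), class = "risk_thresholds")
}

#' Toxic unit of one measurement
#'
#' The toxic unit is the ratio of the measured environmental concentration to
#' the acute EC50 for the organism group, with both on the mg/L scale:
#' `TU = (MEC[ng/L] * 1e-6) / EC50[mg/L]`. TU = 1 means exposure at the
#' median-effect level. Vectorised.
#'
#' @param mec_ng_L Measured concentration(s), ng/L, >= 0.
#' @param ec50_mg_L Acute EC50(s), mg/L, > 0.
#' @return Dimensionless toxic unit(s), zero iff the MEC is zero.
#' @export
#' @examples
#' toxic_unit(95, 0.000095) # exposure exactly at the EC50
toxic_unit <- function(mec_ng_L, ec50_mg_L) {
  if (any(!is.finite(ec50_mg_L) | ec50_mg_L <= 0)) {
    abort_validation("EC50 must be strictly positive.")
  }
  if (any(!is.finite(mec_ng_L) | mec_ng_L < 0)) {
    abort_validation("MEC must be non-negative and finite.")
  }
  (mec_ng_L * NG_TO_MG) / ec50_mg_L
}

#' Toxic units for every detected entry
#'
#' Joins a censored concentration table with a per-compound, per-BQE effect
#' table and computes one toxic unit per detected (non-censored) entry and
#' BQE. Censored entries never produce a toxic unit; compounds without an
#' effect value for a BQE are simply absent for that BQE (they appear in the
#' effect table's exclusion report).
#'
#' @param table Concentration tibble (after [censor_below_mdl()], or with a
#'   `censored` column).
#' @param effect_table Tibble from [build_effect_table()].
#' @param censored_as `"zero"` drops censored entries (default); `"half_mdl"`
#'   includes them at half the MDL for sensitivity analysis.
#' @return Tibble `sample_id`, `compound_id`, `bqe`, `tu`, `ec50_provenance`.
#' @export
compute_toxic_units <- function(table, effect_table, censored_as = c("zero", "half_mdl")) {
  censored_as <- match.arg(censored_as)
  require_columns(table, c("sample_id", "compound_id", "concentration_ng_L"),
                  "Concentration table")
  require_columns(effect_table, c("compound_id", "bqe", "ec50_mg_L", "provenance"),
                  "Effect table")
  if (!"censored" %in% names(table)) table$censored <- FALSE
  table$.value <- effective_concentration(table, censored_as)
  use <- if (censored_as == "zero") !table$censored else rep(TRUE, nrow(table))
  table[use, c("sample_id", "compound_id", ".value")] |>
    inner_join(effect_table, by = "compound_id", relationship = "many-to-many") |>
    mutate(tu = toxic_unit(.data$.value, .data$ec50_mg_L)) |>
    select("sample_id", "compound_id", "bqe", "tu", ec50_provenance = "provenance")
}

#' Mixture toxic-unit sum for one sample and BQE
#'
#' Sums the toxic units of all detected compounds for one sample and one
#' organism group under the concentration-addition assumption. Summation is
#' compensated (Kahan), so the result is invariant to input order.
#' Contributions are returned ranked descending, ties broken by compound id.
#'
#' @param tus Tibble of toxic units (as from [compute_toxic_units()]) for a
#'   single `sample_id` and `bqe`; mixing either is an error.
#' @return A one-row tibble `sample_id`, `bqe`, `tusum`, `n_compounds` with
#'   the ranked contributions tibble attached as attribute `"contributions"`.
#' @export
tusum <- function(tus) {
  require_columns(tus, c("sample_id", "compound_id", "bqe", "tu"), "Toxic-unit table")
  if (nrow(tus) == 0) {
    out <- tibble(sample_id = NA_character_, bqe = NA_character_,
                  tusum = 0, n_compounds = 0L)
    attr(out, "contributions") <- tus
    return(out)
  }
  if (length(unique(tus$sample_id)) > 1 || length(unique(tus$bqe)) > 1) {
    abort_validation("tusum() expects toxic units for a single sample and BQE.")
  }
  contributions <- tus |> arrange(desc(.data$tu), .data$compound_id)
  out <- tibble(
    sample_id = tus$sample_id[1], bqe = tus$bqe[1],
    tusum = kahan_sum(tus$tu), n_compounds = nrow(tus)
  )
  attr(out, "contributions") <- contributions
  out
}

#' Set chronic and acute exceedance flags
#'
#' @param profiles Tibble with at least `bqe` and `tusum`.
#' @param thresholds A [risk_thresholds()].
#' @return `profiles` with logical columns `chronic_exceeded` and
#'   `acute_exceeded` (strict inequality at the threshold).
#' @export
classify_risk <- function(profiles, thresholds = risk_thresholds()) {
  if (!inherits(thresholds, "risk_thresholds")) {
    abort_config("`thresholds` must be a risk_thresholds object.")
  }
  require_columns(profiles, c("bqe", "tusum"), "Risk profiles")
  profiles |>
    mutate(
      chronic_exceeded = .data$tusum > unname(thresholds$chronic[.data$bqe]),
      acute_exceeded = .data$tusum > unname(thresholds$acute[.data$bqe])
    )
}

#' Name the dominant risk contributors
#'
#' Contributors with a toxic unit at or above `min_tu` are listed
#' individually; the remainder is aggregated into a single synthetic
#' `"further compounds"` entry, so that named contributions plus the
#' remainder always sum to the TUsum.
#'
#' @param contributions Tibble `compound_id`, `tu` (one sample and BQE), e.g.
#'   the `"contributions"` attribute of [tusum()] or a filtered slice of a
#'   risk assessment's contribution table.
#' @param min_tu Minimum toxic unit for individual naming; default 0.01.
#' @return A list with `named` (tibble `compound_id`, `tu`, descending) and
#'   `further_tu` (the aggregated remainder).
#' @export
top_contributors <- function(contributions, min_tu = 0.01) {
  require_columns(contributions, c("compound_id", "tu"), "Contributions")
  named <- contributions |>
    filter(.data$tu >= min_tu) |>
    arrange(desc(.data$tu), .data$compound_id) |>
    select("compound_id", "tu")
  further <- kahan_sum(contributions$tu[contributions$tu < min_tu])
  list(named = named, further_tu = further)
}

#' Mixture toxic-risk assessment of a concentration table
#'
#' End-to-end risk pipeline: derive per-compound, per-BQE EC50s through the
#' selection hierarchy, compute toxic units for every detected entry, sum
#' them per sample and organism group under concentration addition, and flag
#' chronic/acute threshold exceedance.
#'
#' @param table Concentration tibble, censored via [censor_below_mdl()]
#'   beforehand (a table without MDLs is accepted and treated as fully
#'   detected).
#' @param library Compound library tibble.
#' @param db An [effect_database()].
#' @param thresholds A [risk_thresholds()].
#' @param censored_as Treatment of censored entries, see
#'   [compute_toxic_units()].
#' @return An object of class `risk_assessment` with elements `profiles`
#'   (sample x BQE tibble with `tusum` and exceedance flags), `contributions`
#'   (ranked per sample x BQE), `exclusions`, `effect_table` and
#'   `thresholds`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
assess_risk <- function(table, library, db = effect_database(),
                        thresholds = risk_thresholds(),
                        censored_as = c("zero", "half_mdl")) {
  censored_as <- match.arg(censored_as)
  require_columns(table, c("sample_id", "compound_id", "concentration_ng_L"),
                  "Concentration table")
  unknown <- setdiff(unique(table$compound_id), library$compound_id)
  if (length(unknown) > 0) {
    abort(paste0("Compound(s) absent from library: ", paste(unknown, collapse = ", ")),
          class = c("meltrisk_unknown_compound", "meltrisk_error"))
  }
  used <- library[library$compound_id %in% table$compound_id, , drop = FALSE]
  effect_table <- build_effect_table(used, db)
  tus <- compute_toxic_units(table, effect_table, censored_as = censored_as)
  contributions <- tus |>
    group_by(.data$sample_id, .data$bqe) |>
    arrange(desc(.data$tu), .data$compound_id, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  profiles <- tus |>
    group_by(.data$sample_id, .data$bqe) |>
    summarise(tusum = kahan_sum(.data$tu), n_compounds = n(), .groups = "drop")
  # samples with nothing detected for a BQE still get a zero-risk row
  all_samples <- unique(table$sample_id)
  if (length(all_samples) > 0) {
    profiles <- tidyr::complete(profiles,
                                sample_id = all_samples, bqe = BQE_LEVELS,
                                fill = list(tusum = 0, n_compounds = 0L))
  }
  profiles <- classify_risk(profiles, thresholds) |>
    arrange(.data$sample_id, .data$bqe)
  structure(
    list(profiles = profiles, contributions = contributions,
         exclusions = attr(effect_table, "exclusions"),
         effect_table = effect_table, thresholds = thresholds),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("<risk_assessment>\n")
  cat("  samples:", length(unique(x$profiles$sample_id)), "\n")
  exc <- x$profiles |>
    group_by(.data$bqe) |>
    summarise(chronic = sum(.data$chronic_exceeded), acute = sum(.data$acute_exceeded),
              .groups = "drop")
  for (i in seq_len(nrow(exc))) {
    cat(sprintf("  %-10s chronic exceedances: %d, acute: %d\n",
                exc$bqe[i], exc$chronic[i], exc$acute[i]))
  }
  if (nrow(x$exclusions) > 0) {
    cat("  excluded compound x BQE pairs:", nrow(x$exclusions), "\n")
  }
  invisible(x)
}
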