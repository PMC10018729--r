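# broom-style tidiers for the result objects.

#' Tidy a risk assessment
#'
#' @param x A `risk_assessment`.
#' @param type `"profiles"` (one row per sample and BQE) or `"contributions"`
#'   (one row per sample, BQE and contributing compound, ranked).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy risk_assessment
#' @export
tidy.risk_assessment <- function(x, type = c("profiles", "contributions"), ...) {
  type <- match.arg(type)
  as_tibble(x[[type]])
}

#' @rdname tidy.risk_assessment
#' @method glance risk_assessment
#' @export
glance.risk_assessment <- function(x, ...) {
  exc <- x$profiles |>
    group_by(.data$bqe) |>
    summarise(chronic = sum(.data$chronic_exceeded),
              acute = sum(.data$acute_exceeded), .groups = "drop")
  wide <- tidyr::pivot_wider(exc, names_from = "bqe",
                             values_from = c("chronic", "acute"))
  dplyr::bind_cols(
    tibble(
      n_samples = length(unique(x$profiles$sample_id)),
      n_compounds = length(unique(x$contributions$compound_id)),
      n_excluded = nrow(x$exclusions)
    ),
    wide
  )
}

#' Tidy a source attribution
#'
#' @param x A `source_attribution`.
#' @param ... Unused.
#' @return Tibble `compound_id`, `rho`, `n`, `source_class`.
#' @method tidy source_attribution
#' @export
tidy.source_attribution <- function(x, ...) as_tibble(x$attribution)

#' @rdname tidy.source_attribution
#' @method glance source_attribution
#' @export
glance.source_attribution <- function(x, ...) {
  counts <- table(factor(x$attribution$source_class, levels = SOURCE_CLASSES))
  dplyr::bind_cols(
    tibble(n_compounds = nrow(x$attribution), cutoff = x$cutoff),
    as_tibble(as.list(counts))
  )
}

#' Tidy a removal result
#'
#' @param x A `removal_result`.
#' @param ... Unused.
#' @return Tibble `compound_id`, loads, `removal_rate`, `bin`.
#' @method tidy removal_result
#' @export
tidy.removal_result <- function(x, ...) as_tibble(x$removal)

#' @rdname tidy.removal_result
#' @method glance removal_result
#' @export
glance.removal_result <- function(x, ...) {
  counts <- table(factor(x$removal$bin, levels = REMOVAL_BINS))
  dplyr::bind_cols(
    tibble(n_compounds = nrow(x$removal), n_undefined = length(x$undefined),
           n_intersection = x$n_intersection),
    as_tibble(as.list(counts))
  )
}
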