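# ggplot2 views of the three result types.

#' Plot per-sample mixture risk with named drivers
#'
#' Stacked bars of the toxic-unit contributions per sample, faceted by BQE,
#' with contributors below `min_tu` aggregated into "further compounds" and
#' the chronic thresholds drawn as dashed lines. The TU axis is log10.
#'
#' @param object A `risk_assessment`.
#' @param min_tu Minimum TU for naming a compound individually.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_assessment
#' @export
autoplot.risk_assessment <- function(object, min_tu = 0.01, ...) {
  contrib <- object$contributions |>
    mutate(compound = if_else(.data$tu >= min_tu, .data$compound_id, "further compounds")) |>
    group_by(.data$sample_id, .data$bqe, .data$compound) |>
    summarise(tu = sum(.data$tu), .groups = "drop")
  th <- tibble(bqe = BQE_LEVELS, chronic = unname(object$thresholds$chronic))
  ggplot2::ggplot(contrib, ggplot2::aes(x = .data$sample_id, y = .data$tu,
                                        fill = .data$compound)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = th, ggplot2::aes(yintercept = .data$chronic),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$bqe), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "toxic units (TUsum)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot flow correlations per compound
#'
#' Bar chart of Spearman coefficients against inlet flow, coloured by source
#' class, with the classification cutoffs marked.
#'
#' @param object A `source_attribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot source_attribution
#' @export
autoplot.source_attribution <- function(object, ...) {
  att <- object$attribution |>
    filter(!is.na(.data$rho)) |>
    arrange(desc(.data$rho)) |>
    mutate(compound_id = factor(.data$compound_id, levels = .data$compound_id))
  ggplot2::ggplot(att, ggplot2::aes(x = .data$compound_id, y = .data$rho,
                                    fill = .data$source_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-object$cutoff, object$cutoff),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Spearman rho vs. inlet flow", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot removal rates per compound
#'
#' @param object A `removal_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot removal_result
#' @export
autoplot.removal_result <- function(object, ...) {
  rem <- object$removal |>
    arrange(desc(.data$removal_rate)) |>
    mutate(compound_id = factor(.data$compound_id, levels = .data$compound_id))
  ggplot2::ggplot(rem, ggplot2::aes(x = .data$compound_id,
                                    y = 100 * .data$removal_rate,
                                    fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0, 50, 80), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "removal rate (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}
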