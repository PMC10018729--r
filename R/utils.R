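# Internal helpers shared across modules.

# Conversion from ng/L to mg/L, applied exactly once, at TU computation.
NG_TO_MG <- 1e-6

BQE_LEVELS <- c("algae", "crustacean", "fish")
CATEGORY_LEVELS <- c("traffic", "pesticide_biocide", "human_consumption", "other")

#' Order-independent compensated summation
#'
#' Sums a numeric vector with Kahan's compensated algorithm after sorting the
#' addends, so the result is a deterministic function of the multiset of
#' values — exactly invariant to permutation of the input. Used for all
#' toxic-unit and load sums so mixture totals are bit-reproducible regardless
#' of row order.
#'
#' @param x Numeric vector; `NA` values are an error (censored entries must be
#'   removed upstream, never passed as `NA`).
#' @return A length-1 double.
#' @export
#' @examples
#' kahan_sum(c(1e16, 1, -1e16))
kahan_sum <- function(x) {
  if (anyNA(x)) {
    abort("kahan_sum() does not accept NA; drop censored entries first.",
      class = "meltrisk_validation_error"
    )
  }
  x <- sort(x, method = "radix")
  s <- 0
  c <- 0
  for (xi in x) {
    y <- xi - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

#' Normalise biological quality element labels
#'
#' Maps common synonyms onto the three canonical BQE labels used throughout
#' the package: `"algae"`, `"crustacean"`, `"fish"`. `"daphnia"` (and
#' `"daphnid"`, `"invertebrate"`) are treated as the crustacean BQE, so input
#' files may use either spelling.
#'
#' @param x Character vector of BQE labels.
#' @return Character vector with values in `c("algae", "crustacean", "fish")`.
#' @export
normalize_bqe <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y[y %in% c("daphnia", "daphnid", "daphnids", "invertebrate", "crustaceans")] <- "crustacean"
  y[y %in% c("green algae", "alga")] <- "algae"
  bad <- setdiff(unique(y), BQE_LEVELS)
  if (length(bad) > 0) {
    abort(
      paste0("Unknown BQE label(s): ", paste(bad, collapse = ", "),
             ". Expected one of: ", paste(BQE_LEVELS, collapse = ", "), "."),
      class = "meltrisk_validation_error"
    )
  }
  y
}

abort_config <- function(msg) abort(msg, class = c("meltrisk_config_error", "meltrisk_error"))
abort_input <- function(msg) abort(msg, class = c("meltrisk_input_error", "meltrisk_error"))
abort_validation <- function(msg) abort(msg, class = c("meltrisk_validation_error", "meltrisk_error"))
abort_schema <- function(msg) abort(msg, class = c("meltrisk_schema_error", "meltrisk_error"))

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema(paste0(
      what, " is missing required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Seeded evaluation that restores the caller's RNG state afterwards, so
# generators are pure functions of (scenario, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort_validation("`seed` must be a single integer.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
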