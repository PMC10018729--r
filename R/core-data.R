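# Data model and I/O for long-format concentration tables, method detection
# limits, censoring, and source-category aggregation.

#' Column schema for concentration tables
#'
#' Describes how the columns of a delimited concentration file map onto the
#' canonical long format (`sample_id`, `compound_id`, `concentration_ng_L`,
#' optional `mdl_ng_L`) and the unit the concentration column is expressed in.
#' All concentrations are stored internally in ng/L; effect concentrations are
#' mg/L and the two meet exactly once, at toxic-unit computation.
#'
#' @param sample_id,compound_id,concentration,mdl Column names in the file.
#'   `mdl` may be absent from the file.
#' @param unit Unit of the concentration (and MDL) column: `"ng/L"`, `"ug/L"`
#'   or `"mg/L"`. Values are converted to ng/L on read.
#' @return A list of class `meltrisk_schema`.
#' @export
conc_schema <- function(sample_id = "sample_id",
                        compound_id = "compound_id",
                        concentration = "concentration_ng_L",
                        mdl = "mdl_ng_L",
                        unit = "ng/L") {
  factor <- c("ng/L" = 1, "ug/L" = 1e3, "mg/L" = 1e6)[[unit]]
  if (is.null(factor) || is.na(factor)) {
    abort_config(paste0("Unknown concentration unit '", unit, "'; use ng/L, ug/L or mg/L."))
  }
  structure(
    list(sample_id = sample_id, compound_id = compound_id,
         concentration = concentration, mdl = mdl,
         unit = unit, to_ng_factor = factor),
    class = "meltrisk_schema"
  )
}

#' Read a long-format concentration table
#'
#' Reads a delimited file of per-sample, per-compound measured environmental
#' concentrations (MECs) and returns the canonical table used by all
#' downstream steps. Rows whose concentration cannot be parsed are dropped
#' with a warning naming their (data) row numbers; negative concentrations are
#' a hard validation error, also naming the rows.
#'
#' @param path Path to a CSV file.
#' @param schema A [conc_schema()] describing the file's columns and unit.
#' @return A tibble with columns `sample_id`, `compound_id`,
#'   `concentration_ng_L`, `mdl_ng_L` (`NA` where the file had none) and
#'   `censored` (all `FALSE`; set by [censor_below_mdl()]).
#' @seealso [censor_below_mdl()], [write_concentration_table()]
#' @export
read_concentration_table <- function(path, schema = conc_schema()) {
  if (!file.exists(path)) abort_input(paste0("Concentration file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c(schema$sample_id, schema$compound_id, schema$concentration),
                  paste0("Concentration file '", path, "'"))
  out <- tibble(
    sample_id = as.character(raw[[schema$sample_id]]),
    compound_id = as.character(raw[[schema$compound_id]]),
    concentration_ng_L = suppressWarnings(as.numeric(raw[[schema$concentration]])) *
      schema$to_ng_factor,
    mdl_ng_L = if (schema$mdl %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[schema$mdl]])) * schema$to_ng_factor
    } else {
      NA_real_
    }
  )
  bad <- which(!is.finite(out$concentration_ng_L))
  if (length(bad) > 0) {
    warn(paste0("Dropped ", length(bad), " unparseable row(s) (data rows: ",
                paste(bad, collapse = ", "), ")."))
    out <- out[-bad, , drop = FALSE]
  }
  neg <- which(out$concentration_ng_L < 0)
  if (length(neg) > 0) {
    abort_validation(paste0(
      "Negative concentration(s) in '", path, "' at data row(s): ",
      paste(neg, collapse = ", ")
    ))
  }
  out$censored <- FALSE
  out
}

#' Write a concentration table to CSV
#'
#' Inverse of [read_concentration_table()] for canonical (ng/L) tables; the
#' `censored` flag is not written, since censoring is derived from the MDL.
#'
#' @param table A concentration tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  require_columns(table, c("sample_id", "compound_id", "concentration_ng_L"),
                  "Concentration table")
  cols <- c("sample_id", "compound_id", "concentration_ng_L")
  if ("mdl_ng_L" %in% names(table) && any(is.finite(table$mdl_ng_L))) {
    cols <- c(cols, "mdl_ng_L")
  }
  readr::write_csv(table[cols], path)
  invisible(path)
}

#' Read a compound library
#'
#' Reads compound metadata: identity, source category, use tags, log Kow and
#' log10 aqueous solubility. Where the `category` cell is empty it is resolved
#' from the use tags via [resolve_category()]; a compound with any
#' traffic-related use is always categorised as traffic.
#'
#' @param path CSV with columns `compound_id`, `name`, `category`, `uses`
#'   (`;`-separated tags), `log_kow`, `log10_solubility_mg_L`; empty cells
#'   mean absent.
#' @return A tibble, one row per compound, with `uses` as a list-column.
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) abort_input(paste0("Compound library not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c("compound_id", "category"), paste0("Compound library '", path, "'"))
  uses <- if ("uses" %in% names(raw)) {
    purrr::map(raw$uses, function(u) {
      if (is.na(u) || !nzchar(u)) character(0) else trimws(strsplit(u, ";", fixed = TRUE)[[1]])
    })
  } else {
    rep(list(character(0)), nrow(raw))
  }
  category <- ifelse(is.na(raw$category) | !nzchar(raw$category),
                     purrr::map_chr(uses, resolve_category),
                     tolower(trimws(raw$category)))
  bad <- setdiff(unique(category), CATEGORY_LEVELS)
  if (length(bad) > 0) {
    abort_validation(paste0("Unknown category value(s): ", paste(bad, collapse = ", ")))
  }
  # any traffic use forces the traffic category, whatever the file says
  has_traffic_use <- purrr::map_lgl(uses, function(u) any(grepl("traffic", u, ignore.case = TRUE)))
  category[has_traffic_use] <- "traffic"
  out <- tibble(
    compound_id = as.character(raw$compound_id),
    name = if ("name" %in% names(raw)) as.character(raw$name) else raw$compound_id,
    category = category,
    uses = uses,
    log_kow = if ("log_kow" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$log_kow))
    } else {
      NA_real_
    },
    log10_solubility_mg_L = if ("log10_solubility_mg_L" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$log10_solubility_mg_L))
    } else {
      NA_real_
    }
  )
  dup <- out$compound_id[duplicated(out$compound_id)]
  if (length(dup) > 0) {
    abort_validation(paste0("Duplicated compound_id in library: ",
                            paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Resolve a source category from use tags
#'
#' Compounds are aggregated by usage and probable source into four classes:
#' traffic, pesticides/biocides, human consumption (pharmaceuticals, food,
#' personal care) and other. A compound with several uses resolves by
#' precedence traffic > pesticide_biocide > human_consumption > other, so any
#' traffic use wins.
#'
#' @param uses Character vector of free-text use tags for one compound.
#' @return One of `"traffic"`, `"pesticide_biocide"`, `"human_consumption"`,
#'   `"other"`.
#' @export
resolve_category <- function(uses) {
  u <- tolower(uses)
  if (any(grepl("traffic|tire|tyre|road|vehicle|fuel|antifreeze|rubber", u))) return("traffic")
  if (any(grepl("pesticide|biocide|herbicide|insecticide|fungicide|rodenticide", u))) {
    return("pesticide_biocide")
  }
  if (any(grepl("pharma|drug|food|personal care|cosmetic|household|consumption|sweetener|stimulant", u))) {
    return("human_consumption")
  }
  "other"
}

#' Read sample metadata
#'
#' @param path CSV with columns `sample_id`, `site_type` (one of `road`,
#'   `background`, `wwtp_influent`, `wwtp_effluent`), `date`, `flow_m3_day`,
#'   `traffic_intensity`; date and positive flow are required for WWTP
#'   samples and checked here.
#' @return A tibble, one row per sample.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) abort_input(paste0("Sample metadata not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c("sample_id", "site_type"), paste0("Sample metadata '", path, "'"))
  out <- tibble(
    sample_id = as.character(raw$sample_id),
    site_type = tolower(trimws(raw$site_type)),
    date = if ("date" %in% names(raw)) as.Date(raw$date) else as.Date(NA),
    flow_m3_day = if ("flow_m3_day" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$flow_m3_day))
    } else {
      NA_real_
    },
    traffic_intensity = if ("traffic_intensity" %in% names(raw)) {
      as.character(raw$traffic_intensity)
    } else {
      NA_character_
    }
  )
  bad <- setdiff(unique(out$site_type),
                 c("road", "background", "wwtp_influent", "wwtp_effluent"))
  if (length(bad) > 0) {
    abort_validation(paste0("Unknown site_type value(s): ", paste(bad, collapse = ", ")))
  }
  wwtp <- out$site_type %in% c("wwtp_influent", "wwtp_effluent")
  if (any(wwtp & (is.na(out$date) | is.na(out$flow_m3_day) | out$flow_m3_day <= 0))) {
    abort_validation("WWTP samples must carry a date and a positive flow_m3_day.")
  }
  out
}

#' Estimate a method detection limit from replicate injections
#'
#' MDL estimation in the style of the US EPA replicate-injection procedure:
#' the one-sided Student-t factor at the requested confidence, for `n - 1`
#' degrees of freedom, times the sample standard deviation of the replicate
#' measurements.
#'
#' @param replicates Numeric vector (>= 2) of replicate low-level
#'   concentration measurements, ng/L.
#' @param confidence One-sided confidence level; default 0.99.
#' @return The MDL in ng/L. Scales linearly with a common factor on the
#'   replicates; zero when all replicates are equal.
#' @export
#' @examples
#' estimate_mdl(c(1.1, 0.9, 1.2, 1.0, 0.8, 1.1, 1.0))
estimate_mdl <- function(replicates, confidence = 0.99) {
  replicates <- as.numeric(replicates)
  if (anyNA(replicates)) abort_validation("Replicates must not contain NA.")
  n <- length(replicates)
  if (n < 2) {
    abort(paste0("MDL estimation needs at least 2 replicates, got ", n, "."),
          class = c("meltrisk_insufficient_data", "meltrisk_error"))
  }
  if (confidence <= 0 || confidence >= 1) abort_validation("`confidence` must be in (0, 1).")
  qt(confidence, df = n - 1) * sd(replicates)
}

#' Flag concentrations below the method detection limit
#'
#' Marks entries with concentration strictly below the compound's MDL as
#' censored. A value exactly equal to the MDL counts as detected. Censored
#' values are retained for audit but contribute zero to every downstream sum
#' and toxic unit (an MDL/2 substitution is available in the aggregation and
#' load functions for sensitivity analysis). Idempotent.
#'
#' @param table Concentration tibble from [read_concentration_table()].
#' @param mdl Optional tibble `compound_id`, `mdl_ng_L` overriding or
#'   supplying per-compound MDLs; otherwise the table's own `mdl_ng_L` column
#'   is used.
#' @param default_mdl Optional MDL (ng/L) for compounds with none. The default
#'   is none: a compound without an MDL is a configuration error, because a
#'   silent default would hide data problems.
#' @return The table with `censored` set and `mdl_ng_L` filled in.
#' @export
censor_below_mdl <- function(table, mdl = NULL, default_mdl = NULL) {
  require_columns(table, c("compound_id", "concentration_ng_L"), "Concentration table")
  if (!"mdl_ng_L" %in% names(table)) table$mdl_ng_L <- NA_real_
  if (!is.null(mdl)) {
    require_columns(mdl, c("compound_id", "mdl_ng_L"), "MDL table")
    table <- table |>
      select(-"mdl_ng_L") |>
      left_join(mdl[c("compound_id", "mdl_ng_L")], by = "compound_id")
  }
  if (!is.null(default_mdl)) {
    table$mdl_ng_L[!is.finite(table$mdl_ng_L)] <- default_mdl
  }
  missing <- unique(table$compound_id[!is.finite(table$mdl_ng_L)])
  if (length(missing) > 0) {
    abort_config(paste0(
      "No MDL for compound(s): ", paste(head(missing, 10), collapse = ", "),
      if (length(missing) > 10) paste0(" (+", length(missing) - 10, " more)") else "",
      ". Provide `mdl` or `default_mdl`."
    ))
  }
  table$censored <- table$concentration_ng_L < table$mdl_ng_L
  table
}

# Concentration a censored entry contributes to sums: 0 by default, MDL/2 for
# sensitivity analysis.
effective_concentration <- function(table, censored_as = c("zero", "half_mdl")) {
  censored_as <- match.arg(censored_as)
  flag <- if ("censored" %in% names(table)) table$censored else FALSE
  if_else(flag,
          if (censored_as == "zero") 0 else table$mdl_ng_L / 2,
          table$concentration_ng_L)
}

#' Aggregate concentrations by source category
#'
#' Sums non-censored concentrations per sample and source category (traffic,
#' pesticide/biocide, human consumption, other) and counts detected
#' compounds. Sums are invariant to row order and to splitting the input
#' across files.
#'
#' @param table Concentration tibble (ideally after [censor_below_mdl()]).
#' @param library Compound library tibble; every compound in `table` must be
#'   present, otherwise an error lists the unknown ids.
#' @param censored_as How censored entries enter sums: `"zero"` (default) or
#'   `"half_mdl"` for sensitivity analysis.
#' @return A tibble `sample_id`, `category`, `total_ng_L`, `n_detected`, with
#'   all four categories present for every sample (zero where nothing was
#'   detected).
#' @seealso [detection_counts()]
#' @export
aggregate_by_category <- function(table, library, censored_as = c("zero", "half_mdl")) {
  censored_as <- match.arg(censored_as)
  require_columns(table, c("sample_id", "compound_id", "concentration_ng_L"),
                  "Concentration table")
  require_columns(library, c("compound_id", "category"), "Compound library")
  unknown <- setdiff(unique(table$compound_id), library$compound_id)
  if (length(unknown) > 0) {
    abort(paste0("Compound(s) absent from library: ", paste(unknown, collapse = ", ")),
          class = c("meltrisk_unknown_compound", "meltrisk_error"))
  }
  samples <- unique(table$sample_id)
  if (length(samples) == 0) {
    return(tibble(sample_id = character(0), category = character(0),
                  total_ng_L = numeric(0), n_detected = integer(0)))
  }
  table$.value <- effective_concentration(table, censored_as)
  detected <- if ("censored" %in% names(table)) !table$censored else rep(TRUE, nrow(table))
  joined <- table |>
    left_join(library[c("compound_id", "category")], by = "compound_id") |>
    mutate(.detected = detected)
  agg <- joined |>
    group_by(.data$sample_id, .data$category) |>
    summarise(total_ng_L = kahan_sum(.data$.value),
              n_detected = sum(.data$.detected), .groups = "drop")
  tidyr::complete(agg,
                  sample_id = samples,
                  category = CATEGORY_LEVELS,
                  fill = list(total_ng_L = 0, n_detected = 0L)) |>
    arrange(.data$sample_id, .data$category)
}

#' Detection counts per sample and per compound
#'
#' @param table Concentration tibble after censoring.
#' @return A list of two tibbles: `by_sample` (`sample_id`, `n_detected`) and
#'   `by_compound` (`compound_id`, `n_detected`), counting non-censored
#'   entries.
#' @export
detection_counts <- function(table) {
  require_columns(table, c("sample_id", "compound_id"), "Concentration table")
  detected <- if ("censored" %in% names(table)) !table$censored else rep(TRUE, nrow(table))
  tbl <- table[detected, , drop = FALSE]
  list(
    by_sample = tbl |> count(.data$sample_id, name = "n_detected"),
    by_compound = tbl |> count(.data$compound_id, name = "n_detected")
  )
}
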