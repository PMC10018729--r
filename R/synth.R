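# Synthetic compound libraries, snow-site concentration tables, effect
# databases and WWTP series with known ground truth. The generators emulate
# the statistical structure the analysis assumes -- a consistent traffic
# fingerprint across road sites, strongly attenuated backgrounds, many
# compounds detected at exactly one site, and a short composite WWTP series
# with flow-driven versus flow-diluted compounds -- so every downstream
# estimator can be checked against planted truth.

#' Generate a synthetic compound library with partial effect-data coverage
#'
#' Creates `n_compounds` compounds split across the four source categories,
#' each with a log Kow and a (negatively Kow-correlated) log10 solubility,
#' and experimental EC50 records for a stated fraction of compounds. Covered
#' compounds get 1-3 records per BQE drawn log-uniformly; the rest carry only
#' a log Kow, so they exercise the QSAR fallback of the selection hierarchy.
#' Deterministic given the seed.
#'
#' @param n_compounds Number of compounds.
#' @param category_mix Named fractions over `traffic`, `pesticide_biocide`,
#'   `human_consumption`, `other`; must sum to 1.
#' @param effect_data_coverage Fraction of compounds with experimental EC50
#'   records (0 to 1).
#' @param seed Integer seed.
#' @param ec50_log10_range log10 range (mg/L) the experimental EC50s are
#'   drawn uniformly over.
#' @return A list with `library` (compound tibble) and `effects`
#'   (experimental effect-record tibble).
#' @export
generate_compound_library <- function(n_compounds = 100,
                                      category_mix = c(traffic = 0.25,
                                                       pesticide_biocide = 0.25,
                                                       human_consumption = 0.35,
                                                       other = 0.15),
                                      effect_data_coverage = 0.4,
                                      seed = 1,
                                      ec50_log10_range = c(-4, 3)) {
  if (length(setdiff(names(category_mix), CATEGORY_LEVELS)) > 0 ||
      any(category_mix < 0) || abs(sum(category_mix) - 1) > 1e-8) {
    abort_validation("`category_mix` must be non-negative fractions over the four categories summing to 1.")
  }
  if (effect_data_coverage < 0 || effect_data_coverage > 1) {
    abort_validation("`effect_data_coverage` must be in [0, 1].")
  }
  with_seed(seed, {
    mix <- category_mix[intersect(CATEGORY_LEVELS, names(category_mix))]
    counts <- floor(mix * n_compounds)
    remainder <- n_compounds - sum(counts)
    if (remainder > 0) {
      extra <- order(mix * n_compounds - counts, decreasing = TRUE)[seq_len(remainder)]
      counts[extra] <- counts[extra] + 1L
    }
    category <- rep(names(counts), counts)
    ids <- sprintf("C%03d", seq_len(n_compounds))
    log_kow <- round(runif(n_compounds, -1, 7), 2)
    log10_sol <- round(4 - 0.8 * log_kow + rnorm(n_compounds, 0, 0.3), 2)
    library <- tibble(
      compound_id = ids,
      name = paste0("compound-", ids),
      category = category,
      uses = purrr::map(category, function(cat) {
        switch(cat,
          traffic = "traffic-related",
          pesticide_biocide = "biocide",
          human_consumption = "pharmaceutical",
          other = "industrial"
        )
      }),
      log_kow = log_kow,
      log10_solubility_mg_L = log10_sol
    )
    n_cov <- round(effect_data_coverage * n_compounds)
    covered <- if (n_cov > 0) sort(sample(ids, n_cov)) else character(0)
    effects <- purrr::map(covered, function(cid) {
      purrr::map(BQE_LEVELS, function(b) {
        k <- sample(1:3, 1)
        tibble(
          compound_id = cid, bqe = b,
          ec50_mg_L = 10^runif(k, ec50_log10_range[1], ec50_log10_range[2]),
          species = paste0("synthetic-species-", seq_len(k)),
          reference = "synthetic"
        )
      }) |> bind_rows()
    }) |> bind_rows()
    if (nrow(effects) == 0) {
      effects <- tibble(compound_id = character(0), bqe = character(0),
                        ec50_mg_L = numeric(0), species = character(0),
                        reference = character(0))
    }
    list(library = library, effects = effects)
  })
}

#' Snow-melt sampling scenario
#'
#' Parameters of the synthetic snow campaign. Defaults emulate the field
#' situation the analysis is designed for: 20 road sites and 3 traffic-free
#' background sites; road-site traffic totals log-normally distributed around
#' 118 ug/L with a coefficient of variation of about 0.37 (range roughly
#' 59-200 ug/L); backgrounds attenuated to a few percent of the road signal;
#' around 60% of compounds detected at exactly one site; concentrations
#' spanning roughly 1 ng/L to tens of ug/L.
#'
#' @param n_road_sites,n_background_sites Site counts.
#' @param traffic_total_ng_L Expected summed traffic-compound concentration
#'   at a road site, ng/L.
#' @param traffic_total_cv Between-site coefficient of variation of the
#'   traffic total (0 for a deterministic fingerprint).
#' @param compound_noise_sdlog Site-by-compound log-normal noise (sd on the
#'   log scale) around the shared fingerprint; 0 for none.
#' @param background_attenuation Multiplicative factor (< 1) applied to
#'   background-site concentrations.
#' @param nontraffic_total_ng_L Expected summed non-traffic concentration at
#'   a road site, ng/L.
#' @param nontraffic_attenuation Background attenuation for non-traffic
#'   compounds.
#' @param singleton_fraction Fraction of library compounds detected at
#'   exactly one site (drawn from the non-traffic compounds).
#' @param mdl_ng_L Method detection limit applied to every compound, ng/L.
#' @param sub_mdl_fraction Fraction of generated entries planted below the
#'   MDL (rounded to a whole number of entries; this is the exact censored
#'   fraction of the output).
#' @param dominant_bqe BQE for which a dominant risk driver is planted at
#'   each road site (requires effect data; `NULL` to skip planting).
#' @param dominance_factor Planted driver TU as a multiple of the summed TU
#'   of everything else at the site.
#' @param seed Integer seed.
#' @return A list of class `snow_scenario`.
#' @export
snow_scenario <- function(n_road_sites = 20,
                          n_background_sites = 3,
                          traffic_total_ng_L = 118000,
                          traffic_total_cv = 0.37,
                          compound_noise_sdlog = 0.15,
                          background_attenuation = 0.03,
                          nontraffic_total_ng_L = 15000,
                          nontraffic_attenuation = 0.2,
                          singleton_fraction = 0.6,
                          mdl_ng_L = 1,
                          sub_mdl_fraction = 0.02,
                          dominant_bqe = "fish",
                          dominance_factor = 5,
                          seed = 1) {
  if (background_attenuation < 0 || singleton_fraction < 0 || singleton_fraction > 1 ||
      sub_mdl_fraction < 0 || sub_mdl_fraction >= 1) {
    abort_validation("Invalid snow scenario fractions.")
  }
  structure(as.list(environment()), class = "snow_scenario")
}

#' Generate synthetic snow-site concentration data with ground truth
#'
#' Road sites share a per-compound traffic fingerprint (log-normal location
#' per compound, one common site-level total deviation, plus optional
#' site-by-compound noise); background sites carry the attenuated fingerprint.
#' Common non-traffic compounds appear at every road site; singleton
#' compounds appear at exactly one random site each. A stated fraction of
#' entries is planted below the MDL (all other entries are clamped to the MDL
#' so the censored fraction is exact), and, when effect data are supplied,
#' one dominant risk driver is planted per road site by setting its
#' concentration so its toxic unit is `dominance_factor` times the summed TU
#' of everything else at that site for the target BQE.
#'
#' @param scenario A [snow_scenario()].
#' @param library Compound tibble (from [generate_compound_library()]).
#' @param effects Experimental effect records used to plant the dominant
#'   driver; `NULL` disables planting.
#' @param db Effect database used when planting drivers; defaults to
#'   `effect_database(effects)`.
#' @return A list with `table` (censored concentration tibble), `meta`
#'   (sample metadata tibble) and `truth`: `category_sums` (non-censored sum
#'   per sample and category), `dominant` (`sample_id`, `compound_id`,
#'   `bqe`), `singletons`, `n_sub_mdl`.
#' @export
generate_snow_samples <- function(scenario, library, effects = NULL, db = NULL) {
  stopifnot(inherits(scenario, "snow_scenario"))
  s <- scenario
  with_seed(s$seed, {
    traffic_ids <- library$compound_id[library$category == "traffic"]
    nontraffic_ids <- setdiff(library$compound_id, traffic_ids)
    if (length(traffic_ids) == 0) abort_validation("Library has no traffic compounds.")
    n_singleton <- round(s$singleton_fraction * nrow(library))
    if (n_singleton > length(nontraffic_ids)) {
      abort_validation("singleton_fraction too large for the library's non-traffic share.")
    }
    singletons <- if (n_singleton > 0) sort(sample(nontraffic_ids, n_singleton)) else character(0)
    common_nt <- setdiff(nontraffic_ids, singletons)

    road_ids <- sprintf("road_%02d", seq_len(s$n_road_sites))
    bg_ids <- sprintf("background_%02d", seq_len(s$n_background_sites))
    sites <- c(road_ids, bg_ids)

    # per-compound fingerprint locations: random weights scaled to the target total
    fingerprint <- function(ids, total) {
      w <- rlnorm(length(ids), 0, 1)
      setNames(total * w / sum(w), ids)
    }
    mu_traffic <- fingerprint(traffic_ids, s$traffic_total_ng_L)
    mu_nt <- if (length(common_nt) > 0) fingerprint(common_nt, s$nontraffic_total_ng_L) else numeric(0)

    sdlog_site <- sqrt(log(1 + s$traffic_total_cv^2))
    site_factor <- setNames(
      exp(rnorm(length(sites), -sdlog_site^2 / 2, sdlog_site)), sites
    )

    entry <- function(site, ids, mu, atten) {
      if (length(ids) == 0) return(NULL)
      noise <- if (s$compound_noise_sdlog > 0) {
        exp(rnorm(length(ids), -s$compound_noise_sdlog^2 / 2, s$compound_noise_sdlog))
      } else {
        rep(1, length(ids))
      }
      tibble(sample_id = site, compound_id = ids,
             concentration_ng_L = atten * mu[ids] * site_factor[[site]] * noise)
    }
    rows <- list()
    for (site in road_ids) {
      rows[[length(rows) + 1]] <- entry(site, traffic_ids, mu_traffic, 1)
      rows[[length(rows) + 1]] <- entry(site, common_nt, mu_nt, 1)
    }
    for (site in bg_ids) {
      rows[[length(rows) + 1]] <- entry(site, traffic_ids, mu_traffic, s$background_attenuation)
      rows[[length(rows) + 1]] <- entry(site, common_nt, mu_nt, s$nontraffic_attenuation)
    }
    # singleton compounds: one random site each, broad log-normal level
    if (length(singletons) > 0) {
      host <- sample(sites, length(singletons), replace = TRUE)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = host, compound_id = singletons,
        concentration_ng_L = rlnorm(length(singletons), log(500), 1.5)
      )
    }
    table <- bind_rows(rows)
    table$mdl_ng_L <- s$mdl_ng_L
    # emitted entries are detections: clamp to the MDL, then plant the exact
    # sub-MDL fraction
    table$concentration_ng_L <- pmax(table$concentration_ng_L, s$mdl_ng_L)

    # dominant risk driver per road site
    dominant <- tibble(sample_id = character(0), compound_id = character(0),
                       bqe = character(0))
    if (!is.null(s$dominant_bqe) && !is.null(effects) && nrow(effects) > 0) {
      if (is.null(db)) db <- effect_database(effects)
      bqe <- normalize_bqe(s$dominant_bqe)
      candidates <- unique(effects$compound_id[normalize_bqe(effects$bqe) == bqe])
      if (length(candidates) == 0) {
        abort_validation("No effect records for the dominant BQE; cannot plant drivers.")
      }
      used <- library[library$compound_id %in% unique(table$compound_id), ]
      eff_tab <- build_effect_table(used, db, bqes = bqe)
      for (site in road_ids) {
        driver <- sample(candidates, 1)
        ec50 <- select_ec50(list(compound_id = driver), bqe, db)$ec50_mg_L
        site_rows <- table$sample_id == site & table$compound_id != driver
        others <- table[site_rows, ] |>
          inner_join(eff_tab, by = "compound_id")
        tu_others <- sum(toxic_unit(others$concentration_ng_L, others$ec50_mg_L))
        target_tu <- max(s$dominance_factor * tu_others, 1e-3)
        conc <- max(target_tu * ec50 / NG_TO_MG, s$mdl_ng_L)
        table <- table[!(table$sample_id == site & table$compound_id == driver), ]
        table <- bind_rows(table, tibble(
          sample_id = site, compound_id = driver,
          concentration_ng_L = conc, mdl_ng_L = s$mdl_ng_L
        ))
        dominant <- bind_rows(dominant,
                              tibble(sample_id = site, compound_id = driver, bqe = bqe))
      }
    }

    # plant the exact sub-MDL fraction (never on a planted driver)
    n_sub <- round(s$sub_mdl_fraction * nrow(table))
    if (n_sub > 0) {
      protected <- paste(dominant$sample_id, dominant$compound_id)
      eligible <- which(!(paste(table$sample_id, table$compound_id) %in% protected))
      if (n_sub > length(eligible)) abort_validation("sub_mdl_fraction too large.")
      idx <- sample(eligible, n_sub)
      table$concentration_ng_L[idx] <- 0.5 * table$mdl_ng_L[idx]
    }
    table <- censor_below_mdl(table)
    table <- table |> arrange(.data$sample_id, .data$compound_id)

    meta <- tibble(
      sample_id = sites,
      site_type = c(rep("road", length(road_ids)), rep("background", length(bg_ids))),
      date = as.Date(NA),
      flow_m3_day = NA_real_,
      traffic_intensity = c(sample(c("low", "medium", "high"), length(road_ids),
                                   replace = TRUE),
                            rep(NA_character_, length(bg_ids)))
    )
    truth_sums <- aggregate_by_category(table, library)
    list(
      table = table, meta = meta,
      truth = list(category_sums = truth_sums, dominant = dominant,
                   singletons = singletons, n_sub_mdl = n_sub)
    )
  })
}

#' WWTP snow-melt scenario
#'
#' Parameters of the synthetic influent/effluent composite series. Defaults
#' emulate a six-day snow-melt window with a rising-then-falling inlet flow,
#' 13 runoff-driven compounds (concentration increasing with flow), 27
#' flow-diluted compounds (concentration decreasing with flow), 23 compounds
#' driven by an unrelated household-source pattern, and per-compound true
#' removal rates spanning full removal (effluent below the MDL), high,
#' medium, low and negative removal in roughly the proportions seen in
#' municipal plants receiving snow melt.
#'
#' @param n_days Number of daily composite samples.
#' @param start_date First sampling date.
#' @param base_flow_m3_day Mean inlet flow.
#' @param flow_amplitude Relative amplitude of the rise-then-fall flow shape.
#' @param flow_m3_day Optional explicit flow series (length `n_days`,
#'   positive), overriding the shape.
#' @param n_runoff,n_diluted,n_mixed Planted set sizes.
#' @param noise_sd_frac Multiplicative noise sd as a fraction of the signal
#'   (0 for exact monotone relations).
#' @param removal_counts Named integer vector over
#'   `c("effluent_below_mdl", "high", "medium", "low", "negative")` giving how
#'   many compounds get a true removal in each class; `NULL` allocates
#'   proportions 13:27:13:6:4 across all compounds.
#' @param mdl_ng_L Detection limit applied to both streams.
#' @param seed Integer seed.
#' @return A list of class `wwtp_scenario`.
#' @export
wwtp_scenario <- function(n_days = 6,
                          start_date = as.Date("2021-02-17"),
                          base_flow_m3_day = 150000,
                          flow_amplitude = 0.45,
                          flow_m3_day = NULL,
                          n_runoff = 13,
                          n_diluted = 27,
                          n_mixed = 23,
                          noise_sd_frac = 0.05,
                          removal_counts = NULL,
                          mdl_ng_L = 1,
                          seed = 1) {
  if (n_days < 3) abort_validation("`n_days` must be at least 3.")
  if (!is.null(flow_m3_day) && (length(flow_m3_day) != n_days || any(flow_m3_day <= 0))) {
    abort_validation("`flow_m3_day` must be a positive vector of length n_days.")
  }
  if (noise_sd_frac < 0 || noise_sd_frac > 0.5) {
    abort_validation("`noise_sd_frac` must be in [0, 0.5].")
  }
  structure(as.list(environment()), class = "wwtp_scenario")
}

# Rise-then-fall daily flow with pairwise-distinct values, so flow ranks are
# unambiguous.
flow_shape <- function(n_days, base, amplitude) {
  peak <- ceiling(0.6 * n_days)
  up <- seq(-1, 1, length.out = peak)
  down <- seq(1, -1, length.out = n_days - peak + 2)[-1]
  shape <- c(up, down)[seq_len(n_days)]
  # tiny deterministic tilt breaks symmetric ties between the limbs
  base * (1 + amplitude * shape + 1e-4 * seq_len(n_days))
}

# Permutation of 1..n whose ranks are (as close as possible to) Spearman-
# uncorrelated with the flow ranks; exhaustive for n <= 7, seeded search
# otherwise. Used as the day pattern of the household-driven ("mixed")
# compounds, so that class is rank-orthogonal to flow by construction.
zero_rho_pattern <- function(flow) {
  n <- length(flow)
  fr <- rank(flow)
  score <- function(p) abs(cor(p, fr))
  if (n <= 7) {
    perms <- permutations_of(n)
    sc <- vapply(perms, score, numeric(1))
    best <- perms[[which.min(sc)]]
  } else {
    best <- sample(n)
    best_sc <- score(best)
    for (i in seq_len(5000)) {
      cand <- sample(n)
      s <- score(cand)
      if (s < best_sc) {
        best <- cand
        best_sc <- s
      }
      if (best_sc == 0) break
    }
  }
  best
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      out[[k]] <- c(first, rest[p])
      k <- k + 1L
    }
  }
  out
}

#' Generate a synthetic WWTP influent/effluent series with ground truth
#'
#' Influent concentrations follow the planted flow relation per compound:
#' proportional to flow (runoff-driven), inversely proportional to flow
#' (diluted by runoff), or proportional to a shared household-source day
#' pattern chosen to be rank-uncorrelated with flow (mixed). Effluent
#' concentrations are the influent scaled by `1 - true_removal` day by day
#' (loads redistributed proportionally), then censored at the MDL; the
#' full-removal class is constructed so every effluent day falls below the
#' MDL. At zero noise every downstream estimator recovers the planted truth
#' exactly.
#'
#' @param scenario A [wwtp_scenario()].
#' @param library Compound tibble; must contain at least
#'   `n_runoff + n_diluted + n_mixed` compounds.
#' @return A list with `influent` and `effluent` (tibbles `date`, `stream`,
#'   `flow_m3_day`, `compound_id`, `concentration_ng_L`, `mdl_ng_L`,
#'   `censored`), `flow` (tibble `date`, `flow_m3_day`) and `truth` (tibble
#'   `compound_id`, `source_class_true`, `true_removal`, `bin_true`).
#' @export
generate_wwtp_series <- function(scenario, library) {
  stopifnot(inherits(scenario, "wwtp_scenario"))
  s <- scenario
  n_total <- s$n_runoff + s$n_diluted + s$n_mixed
  if (nrow(library) < n_total) {
    abort_validation(paste0("Library has ", nrow(library), " compounds; scenario needs ",
                            n_total, "."))
  }
  with_seed(s$seed, {
    dates <- as.Date(s$start_date) + seq_len(s$n_days) - 1
    flow <- s$flow_m3_day %||% flow_shape(s$n_days, s$base_flow_m3_day, s$flow_amplitude)
    ids <- sample(library$compound_id, n_total)
    runoff_ids <- ids[seq_len(s$n_runoff)]
    diluted_ids <- ids[s$n_runoff + seq_len(s$n_diluted)]
    mixed_ids <- ids[s$n_runoff + s$n_diluted + seq_len(s$n_mixed)]
    pattern <- 0.5 + zero_rho_pattern(flow) / s$n_days

    # removal-class allocation (largest remainder on the default proportions)
    counts <- s$removal_counts
    if (is.null(counts)) {
      prop <- c(effluent_below_mdl = 13, high = 27, medium = 13, low = 6, negative = 4)
      prop <- prop / sum(prop)
      counts <- floor(prop * n_total)
      left <- n_total - sum(counts)
      if (left > 0) {
        extra <- order(prop * n_total - counts, decreasing = TRUE)[seq_len(left)]
        counts[extra] <- counts[extra] + 1L
      }
    }
    if (sum(counts) != n_total || length(setdiff(names(counts), REMOVAL_BINS)) > 0) {
      abort_validation("`removal_counts` must cover the removal bins and sum to the compound total.")
    }
    bin_true <- sample(rep(names(counts), counts))
    # mean influent level per compound, ng/L; floored so that partial-removal
    # effluent stays detectable on every day (only the full-removal class is
    # meant to fall below the MDL)
    level <- pmax(rlnorm(n_total, log(800), 0.8), 200 * s$mdl_ng_L)

    noise <- function(k) {
      if (s$noise_sd_frac > 0) 1 + rnorm(k, 0, s$noise_sd_frac) else rep(1, k)
    }
    conc_for <- function(cid_idx) {
      cid <- ids[cid_idx]
      base <- if (cid %in% runoff_ids) {
        flow / mean(flow)
      } else if (cid %in% diluted_ids) {
        mean(flow) / flow
      } else {
        pattern
      }
      pmax(level[cid_idx] * base * noise(s$n_days), s$mdl_ng_L)
    }
    infl_conc <- vapply(seq_len(n_total), conc_for, numeric(s$n_days))

    true_removal <- numeric(n_total)
    for (j in seq_len(n_total)) {
      true_removal[j] <- switch(bin_true[j],
        effluent_below_mdl = 1 - 0.4 * s$mdl_ng_L / max(infl_conc[, j]),
        high = runif(1, 0.85, 0.98),
        medium = runif(1, 0.55, 0.78),
        low = runif(1, 0.05, 0.45),
        negative = runif(1, -0.3, -0.05)
      )
    }
    effl_conc <- sweep(infl_conc, 2, 1 - true_removal, `*`)

    long <- function(conc, stream) {
      tibble(
        date = rep(dates, n_total),
        stream = stream,
        flow_m3_day = rep(flow, n_total),
        compound_id = rep(ids, each = s$n_days),
        concentration_ng_L = as.vector(conc),
        mdl_ng_L = s$mdl_ng_L
      ) |> censor_below_mdl()
    }
    influent <- long(infl_conc, "influent")
    effluent <- long(effl_conc, "effluent")
    truth <- tibble(
      compound_id = ids,
      source_class_true = dplyr::case_when(
        ids %in% runoff_ids ~ "runoff_dominated",
        ids %in% diluted_ids ~ "diluted_other_source",
        TRUE ~ "mixed"
      ),
      true_removal = true_removal,
      bin_true = bin_true
    )
    list(influent = influent, effluent = effluent,
         flow = tibble(date = dates, flow_m3_day = flow),
         truth = truth)
  })
}
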