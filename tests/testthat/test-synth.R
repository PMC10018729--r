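test_that("generators are deterministic functions of scenario and seed", {
  a <- generate_compound_library(seed = 5)
  b <- generate_compound_library(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$library$log_kow,
                         generate_compound_library(seed = 6)$library$log_kow))

  s1 <- generate_snow_samples(snow_scenario(seed = 5), a$library, a$effects)
  s2 <- generate_snow_samples(snow_scenario(seed = 5), a$library, a$effects)
  expect_identical(s1, s2)

  w1 <- generate_wwtp_series(wwtp_scenario(seed = 5), a$library)
  w2 <- generate_wwtp_series(wwtp_scenario(seed = 5), a$library)
  expect_identical(w1, w2)

  # the generator leaves the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_compound_library(seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("effect-data coverage controls which selection branch is taken", {
  full <- generate_compound_library(n_compounds = 30, effect_data_coverage = 1,
                                    seed = 8)
  tab_full <- build_effect_table(full$library, effect_database(full$effects))
  expect_true(all(tab_full$provenance == "experimental"))

  none <- generate_compound_library(n_compounds = 30, effect_data_coverage = 0,
                                    seed = 8)
  tab_none <- build_effect_table(none$library, effect_database(none$effects))
  expect_true(all(tab_none$provenance %in% c("predicted", "solubility_capped")))

  expect_error(generate_compound_library(category_mix = c(traffic = 0.7, other = 0.7)),
               class = "meltrisk_validation_error")
})

test_that("snow generator places singletons and separates road from background", {
  gen <- generate_compound_library(n_compounds = 100, seed = 12)
  snow <- generate_snow_samples(
    snow_scenario(singleton_fraction = 0.5, sub_mdl_fraction = 0, seed = 12),
    gen$library, effects = NULL
  )
  counts <- dplyr::count(snow$table, compound_id)
  singles <- counts$compound_id[counts$n == 1]
  expect_equal(sort(intersect(singles, snow$truth$singletons)),
               snow$truth$singletons)
  expect_length(snow$truth$singletons, 50)

  # degenerate scenario: no attenuation, no noise -> identical traffic sums
  flat <- generate_snow_samples(
    snow_scenario(background_attenuation = 1, traffic_total_cv = 0,
                  compound_noise_sdlog = 0, singleton_fraction = 0,
                  sub_mdl_fraction = 0, seed = 3),
    gen$library, effects = NULL
  )
  traffic <- flat$truth$category_sums |> dplyr::filter(category == "traffic")
  expect_equal(max(traffic$total_ng_L) - min(traffic$total_ng_L), 0, tolerance = 1e-9)

  # default scenario: every road traffic sum above every background sum
  for (seed in 1:25) {
    s <- generate_snow_samples(snow_scenario(seed = seed), gen$library, effects = NULL)
    tr <- s$truth$category_sums |> dplyr::filter(category == "traffic")
    road <- tr$total_ng_L[grepl("^road", tr$sample_id)]
    bg <- tr$total_ng_L[grepl("^background", tr$sample_id)]
    expect_gt(min(road), max(bg))
  }
})

test_that("snow concentrations sit in the field-realistic range", {
  gen <- generate_compound_library(n_compounds = 100, seed = 14)
  # drivers are deliberate outliers, so check the fingerprint without them
  snow <- generate_snow_samples(snow_scenario(seed = 14), gen$library, effects = NULL)
  detected <- snow$table$concentration_ng_L[!snow$table$censored]
  expect_gte(min(detected), 1)      # at or above the MDL
  tr <- snow$truth$category_sums |>
    dplyr::filter(category == "traffic", grepl("^road", sample_id))
  # road traffic totals on the tens-to-hundreds of ug/L scale
  expect_true(all(tr$total_ng_L > 2e4 & tr$total_ng_L < 1e6))
})

test_that("wwtp generator round-trips planted truth exactly at zero noise", {
  gen <- generate_compound_library(n_compounds = 80, seed = 6)
  ww <- generate_wwtp_series(wwtp_scenario(noise_sd_frac = 0, seed = 6), gen$library)

  # planted monotone relations give exact +/-1 correlations
  att <- tidy(attribute_sources(ww$influent)) |>
    dplyr::inner_join(ww$truth, by = "compound_id")
  expect_true(all(att$rho[att$source_class_true == "runoff_dominated"] == 1))
  expect_true(all(att$rho[att$source_class_true == "diluted_other_source"] == -1))
  expect_equal(att$source_class, att$source_class_true)

  # removal rates recovered exactly, including the negative class;
  # full-removal compounds land in the effluent-below-MDL bin
  rem <- tidy(estimate_removal(ww$influent, ww$effluent)) |>
    dplyr::inner_join(ww$truth, by = "compound_id")
  est <- rem$removal_rate[rem$bin_true != "effluent_below_mdl"]
  tru <- rem$true_removal[rem$bin_true != "effluent_below_mdl"]
  expect_equal(est, tru, tolerance = 1e-12)
  expect_equal(rem$bin, rem$bin_true)
  expect_true(any(rem$bin == "negative"))
  expect_true(any(rem$bin == "effluent_below_mdl"))

  # explicit round-trip cases: 99% removal and a planted negative removal
  ww2 <- generate_wwtp_series(
    wwtp_scenario(noise_sd_frac = 0, seed = 2,
                  n_runoff = 2, n_diluted = 2, n_mixed = 2,
                  removal_counts = c(effluent_below_mdl = 1, high = 2, medium = 1,
                                     low = 1, negative = 1)),
    gen$library
  )
  rem2 <- tidy(estimate_removal(ww2$influent, ww2$effluent)) |>
    dplyr::inner_join(ww2$truth, by = "compound_id")
  neg <- rem2[rem2$bin_true == "negative", ]
  expect_equal(neg$removal_rate, neg$true_removal, tolerance = 1e-12)
  expect_equal(neg$bin, "negative")
})

test_that("planted source classes are recovered under low noise across seeds", {
  gen <- generate_compound_library(n_compounds = 80, seed = 10)
  ok <- 0L
  total <- 0L
  for (seed in 1:20) {
    ww <- generate_wwtp_series(wwtp_scenario(noise_sd_frac = 0.08, seed = seed),
                               gen$library)
    att <- tidy(attribute_sources(ww$influent)) |>
      dplyr::inner_join(ww$truth, by = "compound_id")
    planted <- att[att$source_class_true != "mixed", ]
    ok <- ok + sum(planted$source_class == planted$source_class_true)
    total <- total + nrow(planted)
  }
  expect_gte(ok / total, 0.95)
})
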