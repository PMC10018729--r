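test_that("concentration tables round-trip through CSV with unit conversion", {
  tbl <- tiny_conc_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(tbl, path)
  back <- read_concentration_table(path)
  expect_equal(back[names(tbl)], tbl)

  # a ug/L file converts to ng/L on read
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(sample_id = "s1", compound_id = "T1", conc_ug_L = 0.01),
    path2
  )
  back2 <- read_concentration_table(
    path2, conc_schema(concentration = "conc_ug_L", unit = "ug/L")
  )
  expect_equal(back2$concentration_ng_L, 10)

  # round trip on randomly generated canonical tables
  set.seed(42)
  for (i in 1:5) {
    n <- sample(3:30, 1)
    tab <- tibble::tibble(
      sample_id = paste0("s", sample(1:5, n, replace = TRUE)),
      compound_id = paste0("c", seq_len(n)),
      concentration_ng_L = round(10^runif(n, -0.1, 4.9), 6),
      mdl_ng_L = 1, censored = FALSE
    )
    p <- withr::local_tempfile(fileext = ".csv")
    write_concentration_table(tab, p)
    expect_equal(read_concentration_table(p)[names(tab)], tab)
  }
})

test_that("malformed concentration files are rejected with row context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,compound_id", "s1,T1"), path)
  expect_error(read_concentration_table(path), class = "meltrisk_schema_error")

  writeLines(c("sample_id,compound_id,concentration_ng_L",
               "s1,T1,10", "s1,T2,-4", "s2,T1,2"), path)
  expect_error(read_concentration_table(path), "row\\(s\\): 2",
               class = "meltrisk_validation_error")

  writeLines(c("sample_id,compound_id,concentration_ng_L",
               "s1,T1,10", "s1,T2,not-a-number"), path)
  expect_warning(tbl <- read_concentration_table(path), "rows: 2")
  expect_equal(nrow(tbl), 1)
})

test_that("censoring uses a strict below-MDL rule and is idempotent", {
  tbl <- tibble::tibble(
    sample_id = "s1", compound_id = c("a", "b", "c"),
    concentration_ng_L = c(2, 1, 4), mdl_ng_L = 2
  )
  out <- censor_below_mdl(tbl)
  # exactly at the MDL counts as detected; strictly below is censored
  expect_equal(out$censored, c(FALSE, TRUE, FALSE))
  expect_equal(censor_below_mdl(out), out)
  # censored values are retained for audit
  expect_equal(out$concentration_ng_L, tbl$concentration_ng_L)

  no_mdl <- tbl[, c("sample_id", "compound_id", "concentration_ng_L")]
  expect_error(censor_below_mdl(no_mdl), class = "meltrisk_config_error")
  with_default <- censor_below_mdl(no_mdl, default_mdl = 3)
  expect_equal(with_default$censored, c(TRUE, TRUE, FALSE))
  # an external MDL table overrides the column
  ext <- censor_below_mdl(tbl, mdl = tibble::tibble(compound_id = c("a", "b", "c"),
                                                    mdl_ng_L = c(10, 0.5, 10)))
  expect_equal(ext$censored, c(TRUE, FALSE, TRUE))
})

test_that("generated tables carry exactly the planted censored fraction", {
  gen <- generate_compound_library(n_compounds = 60, seed = 11)
  snow <- generate_snow_samples(
    snow_scenario(sub_mdl_fraction = 0.05, seed = 11),
    gen$library, gen$effects
  )
  expect_equal(sum(snow$table$censored), snow$truth$n_sub_mdl)
  expect_equal(sum(snow$table$censored), round(0.05 * nrow(snow$table)))
})

test_that("MDL estimation matches the one-sided t-factor on replicate sd", {
  expect_equal(estimate_mdl(rep(3.2, 5)), 0)
  reps <- c(1.1, 0.9, 1.2, 1.0, 0.8, 1.1, 1.0)
  # 7 replicates: one-sided 99% t factor for 6 df is 3.143
  expect_equal(estimate_mdl(reps) / sd(reps), 3.143, tolerance = 1e-3)
  # scale equivariance
  expect_equal(estimate_mdl(2 * reps), 2 * estimate_mdl(reps))
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(sample(2:12, 1))
    k <- runif(1, 0.1, 10)
    expect_equal(estimate_mdl(k * x), k * estimate_mdl(x), tolerance = 1e-12)
  }
  expect_error(estimate_mdl(1.0), class = "meltrisk_insufficient_data")
})

test_that("category aggregation is additive, complete and order-invariant", {
  lib <- tiny_library()
  empty <- tiny_conc_table()[0, ]
  agg0 <- aggregate_by_category(empty, lib)
  expect_equal(nrow(agg0), 0)

  tbl <- tiny_conc_table()
  agg <- aggregate_by_category(tbl, lib)
  expect_equal(agg$total_ng_L[agg$sample_id == "s1" & agg$category == "traffic"], 30)
  expect_equal(agg$n_detected[agg$sample_id == "s1" & agg$category == "traffic"], 2L)
  # every sample gets all four categories, zero-filled
  expect_equal(nrow(agg), 2 * 4)
  expect_equal(agg$total_ng_L[agg$sample_id == "s2" & agg$category == "other"], 0)

  # row order and file splitting do not change sums
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(aggregate_by_category(shuffled, lib), agg)
  split_agg <- aggregate_by_category(dplyr::bind_rows(tbl[1:2, ], tbl[3:4, ]), lib)
  expect_equal(split_agg, agg)

  # censored entries contribute zero but remain auditable
  cens <- tbl
  cens$censored[1] <- TRUE
  agg_c <- aggregate_by_category(cens, lib)
  expect_equal(agg_c$total_ng_L[agg_c$sample_id == "s1" & agg_c$category == "traffic"], 20)
  # MDL/2 sensitivity option
  agg_h <- aggregate_by_category(cens, lib, censored_as = "half_mdl")
  expect_equal(agg_h$total_ng_L[agg_h$sample_id == "s1" & agg_h$category == "traffic"], 20.5)

  expect_error(
    aggregate_by_category(dplyr::mutate(tbl, compound_id = "nope"), lib),
    class = "meltrisk_unknown_compound"
  )
})

test_that("library reading resolves categories with traffic precedence", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "compound_id,name,category,uses,log_kow,log10_solubility_mg_L",
    "a,alpha,,tire wear;herbicide,3.2,1.0",
    "b,beta,,herbicide;pharmaceutical,2.0,",
    "c,gamma,human_consumption,pharmaceutical,1.0,2.5",
    "d,delta,,unknown-tag,,"
  ), path)
  lib <- read_compound_library(path)
  expect_equal(lib$category, c("traffic", "pesticide_biocide", "human_consumption", "other"))
  expect_true(is.na(lib$log_kow[4]))
  expect_true(is.na(lib$log10_solubility_mg_L[2]))
  # a stated non-traffic category is overridden by a traffic use tag
  writeLines(c("compound_id,name,category,uses,log_kow,log10_solubility_mg_L",
               "a,alpha,other,antifreeze;traffic fluid,1,1"), path)
  expect_equal(read_compound_library(path)$category, "traffic")
  # duplicated ids are rejected
  writeLines(c("compound_id,name,category,uses,log_kow,log10_solubility_mg_L",
               "a,alpha,other,,1,1", "a,alpha2,other,,1,1"), path)
  expect_error(read_compound_library(path), class = "meltrisk_validation_error")
})

test_that("sample metadata validates WWTP date and flow requirements", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,site_type,date,flow_m3_day,traffic_intensity",
               "r1,road,,,high",
               "w1,wwtp_influent,2021-02-17,150000,"), path)
  meta <- read_sample_meta(path)
  expect_equal(meta$site_type, c("road", "wwtp_influent"))
  writeLines(c("sample_id,site_type,date,flow_m3_day,traffic_intensity",
               "w1,wwtp_influent,2021-02-17,,"), path)
  expect_error(read_sample_meta(path), class = "meltrisk_validation_error")
})
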