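# Inference layer: pair correlations, the homogeneity battery, model
# selection, sex limitation and the bivariate correlation analysis.

test_that("pair correlations behave at the extremes", {
  cfg <- small_ae_config(h2 = 0.4, n = c(MZF = 80, DZF = 80),
                         n_singletons = 0L)
  ds <- simulate_families(cfg, seed = 2)
  d <- ds$data
  # duplicated member values give correlation 1
  d2 <- d
  for (f in unique(d2$family_id)) {
    rows <- which(d2$family_id == f)
    d2$hm_log[rows[2]] <- d2$hm_log[rows[1]]
  }
  dup <- twin_dataset(d2, traits = "hm_log")
  expect_equal(pair_correlation(dup, "hm_log", "MZ", "pearson"), 1,
               tolerance = 1e-12)
  # independent members: |r| below 3 / sqrt(n_pairs)
  cfg0 <- small_ae_config(h2 = 0, n = c(MZF = 1500), n_singletons = 0L)
  ds0 <- simulate_families(cfg0, seed = 13)
  r0 <- pair_correlation(ds0, "hm_log", "MZ", "pearson")
  expect_lt(abs(r0), 3 / sqrt(1500))
  # ML and double-entry Pearson agree on complete balanced data
  r_ml <- pair_correlation(ds, "hm_log", "MZ", "ml")
  r_pe <- pair_correlation(ds, "hm_log", "MZ", "pearson")
  expect_equal(r_ml, r_pe, tolerance = 0.02)
  expect_error(pair_correlation(ds, "hm_log", "DZOS"), "pairs")
})

test_that("homogeneity battery returns the documented tests", {
  cfg <- small_ae_config(beta_sex = 0.3,
                         n = c(MZF = 60, MZM = 60, DZF = 60, DZM = 60,
                               DZOS = 60), n_singletons = 20L)
  ds <- simulate_families(cfg, seed = 10)
  ds$data$age_scan <- round(ds$data$age_scan, 3)
  bat <- homogeneity_battery(ds, "hm_log",
                             covariates = c("sex_male", "age_scan"))
  expect_setequal(
    bat$test,
    c("birth_order", "sex_groups", "quantitative_sex_limitation",
      "qualitative_sex_limitation", "presence_genetic_factors",
      "familial_aggregation", "covariate_sex_male", "covariate_age_scan"))
  expect_true(all(bat$p >= 0 & bat$p <= 1, na.rm = TRUE))
  expect_true(all(bat$statistic >= -1e-6, na.rm = TRUE))
  expect_equal(bat$df[bat$test == "quantitative_sex_limitation"], 2L)
  expect_equal(bat$df[bat$test == "presence_genetic_factors"], 1L)
  # the generating sex effect is recovered by the covariate screen
  expect_lt(abs(bat$estimate[bat$test == "covariate_sex_male"] - 0.3), 0.12)
  # genetic structure is detected at this effect size and n
  expect_lt(bat$p[bat$test == "presence_genetic_factors"], 0.05)
})

test_that("battery skips tests whose groups are absent", {
  cfg <- small_ae_config(n = c(MZF = 50, DZF = 50), n_singletons = 0L)
  ds <- simulate_families(cfg, seed = 11)
  bat <- homogeneity_battery(ds, "hm_log", covariates = "age_scan")
  qsl <- bat[bat$test == "quantitative_sex_limitation", ]
  expect_true(is.na(qsl$p))
  expect_match(qsl$note, "sexes")
  expect_true(is.na(bat$p[bat$test == "qualitative_sex_limitation"]))
})

test_that("null-true covariate test has approximately uniform p-values", {
  # scaled-down calibration study for the battery: the sex-covariate LRT
  # under a no-effect generator
  ps <- vapply(1:150, function(s) {
    cfg <- small_ae_config(beta_sex = 0,
                           n = c(MZF = 40, MZM = 40, DZF = 40, DZM = 40),
                           n_singletons = 0L)
    ds <- simulate_families(cfg, seed = 1000 + s)
    sp_full <- saturated_model("hm_log", covariates = "sex_male")
    full <- fit_model(ds, sp_full, seed = 1, n_starts = 2L)
    nested <- fit_model(ds, sp_full, seed = 1, n_starts = 2L,
                        fix = c(b.hm_log.sex_male = 0))
    lrt(full, nested, refit = list(dataset = ds))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("model selection prefers the generating AE structure", {
  wins <- 0L
  for (s in 1:12) {
    cfg <- small_ae_config(h2 = 0.4,
                           n = c(MZF = 120, MZM = 76, DZF = 120, DZM = 76,
                                 DZOS = 104), n_singletons = 0L)
    ds <- simulate_families(cfg, seed = 500 + s)
    res <- heritability_analysis(ds, "hm_log", ci = FALSE, seed = 1)
    if (res$selected == "AE") wins <- wins + 1L
    expect_true(res$selected != "E" || res$h2 == 0)
  }
  expect_gte(wins, 9L)
})

test_that("sex-limitation analysis recovers sex-specific covariances", {
  cfg <- preset("G-SEXLIM-MH")
  ds <- simulate_families(cfg, seed = 77)
  res <- sex_limitation_analysis(ds, "swan_mh", covariates = "sex_male",
                                 seed = 1)
  expect_true(res$general$converged)
  expect_equal(unname(res$implied_cov$F["MZ"]), 0.97, tolerance = 0.25)
  expect_gt(res$implied_cov$F["MZ"], res$implied_cov$M["MZ"])
  expect_equal(res$rg_mf, 1)
  # equal-parameter data: general model cannot be much better
  cfg0 <- small_ae_config(n = c(MZF = 60, MZM = 60, DZF = 60, DZM = 60,
                                DZOS = 60), n_singletons = 0L)
  ds0 <- simulate_families(cfg0, seed = 19)
  res0 <- sex_limitation_analysis(ds0, "hm_log", components = c("A", "E"),
                                  seed = 1)
  expect_gte(res0$test$p, 0)
  expect_equal(res0$test$df, 2L)
})

test_that("cross-trait analysis returns coherent correlations and tests", {
  cfg <- small_biv_config(rg = 0.5, re = 0.2,
                          n = c(MZF = 120, MZM = 60, DZF = 90, DZM = 45,
                                DZOS = 60))
  ds <- simulate_families(cfg, seed = 23)
  res <- cross_trait_analysis(ds, c("hm_log", "swan_mi"),
                              covariates = "sex_male", ci = TRUE, seed = 1)
  # the AE identity ties the three correlations together
  st <- res$fit$standardized
  h2 <- res$fit$estimates[c("sh.A.hm_log", "sh.A.swan_mi")]
  expect_equal(st$rp,
               st$rg * sqrt(prod(h2)) + st$re * sqrt(prod(1 - h2)),
               tolerance = 1e-8)
  expect_true(res$ci$rg[1] <= st$rg && st$rg <= res$ci$rg[2])
  expect_true(res$tests$rg$p < 0.05)   # strong simulated pleiotropy
  expect_equal(res$tests$rg$df, 1L)
  expect_equal(res$tests$rp$df, 1L)
  # near-duplicated traits give correlations near 1
  d <- ds$data
  d$swan_mi <- d$hm_log + rnorm(nrow(d), 0, 0.02)
  dup <- twin_dataset(d, traits = c("hm_log", "swan_mi"))
  res2 <- cross_trait_analysis(dup, c("hm_log", "swan_mi"),
                               covariates = character(0), ci = FALSE,
                               seed = 1)
  expect_gt(res2$rp, 0.98)
  expect_gt(res2$rg, 0.95)
})

test_that("zero cross-path data give rg CIs covering zero", {
  cfg <- small_biv_config(rg = 0, re = 0)
  ds <- simulate_families(cfg, seed = 29)
  res <- cross_trait_analysis(ds, c("hm_log", "swan_mi"),
                              covariates = character(0), ci = TRUE,
                              seed = 1)
  expect_true(res$ci$rg[1] <= 0 && 0 <= res$ci$rg[2])
})
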