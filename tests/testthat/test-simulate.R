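# Synthetic-data generator: determinism, implied-moment convergence,
# missingness, Likert discretisation and motion-parameter fixtures.

test_that("simulation is deterministic given the seed", {
  cfg <- small_ae_config()
  a <- simulate_families(cfg, seed = 42)
  b <- simulate_families(cfg, seed = 42)
  expect_identical(a$data, b$data)
  c2 <- simulate_families(cfg, seed = 43)
  expect_false(identical(a$data$hm_log, c2$data$hm_log))
})

test_that("empirical moments converge to the implied pair moments", {
  cfg <- small_ae_config(h2 = 0.4, v = 1,
                         n = c(MZF = 50000, DZF = 50000), n_singletons = 0L)
  ds <- simulate_families(cfg, seed = 55)
  d <- ds$data
  for (g in c("MZF", "DZF")) {
    dd <- d[d$zygosity == g, ]
    y <- matrix(dd$hm_log, ncol = 2, byrow = TRUE)
    target <- if (g == "MZF") 0.4 else 0.2
    expect_lt(abs(cov(y[, 1], y[, 2]) - target), 0.01)
    expect_lt(abs(var(as.numeric(y)) - 1), 0.02)
  }
})

test_that("MZ component scores are shared exactly", {
  cfg <- small_ae_config(h2 = 1, n = c(MZF = 50), n_singletons = 0L)
  # pure-A trait: MZ co-twins must be identical up to the mean model
  ds <- simulate_families(cfg, seed = 1)
  y <- matrix(ds$data$hm_log, ncol = 2, byrow = TRUE)
  expect_equal(y[, 1], y[, 2], tolerance = 1e-12)
})

test_that("all-E configurations give independent co-twins", {
  cfg <- small_ae_config(h2 = 0, n = c(MZF = 20000), n_singletons = 0L)
  ds <- simulate_families(cfg, seed = 9)
  y <- matrix(ds$data$hm_log, ncol = 2, byrow = TRUE)
  expect_lt(abs(cor(y[, 1], y[, 2])), 0.02)
})

test_that("zero contrast and absent contrast generate identical cohorts", {
  cfg0 <- small_ae_config()
  cfg1 <- cfg0; cfg1$contrast <- 0
  expect_identical(simulate_families(cfg0, seed = 3)$data,
                   simulate_families(cfg1, seed = 3)$data)
})

test_that("negative contrast deflates the DZ correlation below ADE bounds", {
  v <- 1
  cfg <- generating_config(
    "swan_si", c(MZF = 15000, DZF = 15000),
    sigma = list(D = matrix(0.6 * v), E = matrix(0.4 * v)),
    contrast = -0.15,
    mean = list(intercept = c(swan_si = 0),
                beta = matrix(0, 1, 0, dimnames = list("swan_si", NULL))))
  ds <- simulate_families(cfg, seed = 17)
  d <- ds$data
  rs <- sapply(c("MZF", "DZF"), function(g) {
    y <- matrix(d$swan_si[d$zygosity == g], ncol = 2, byrow = TRUE)
    cor(y[, 1], y[, 2])
  })
  s <- -0.15
  robs <- function(cc) (cc * (1 + s^2) + 2 * s * v) /
    (v * (1 + s^2) + 2 * s * cc)
  expect_lt(abs(rs[["MZF"]] - robs(0.6)), 0.02)
  expect_lt(abs(rs[["DZF"]] - robs(0.15)), 0.02)
  expect_lt(rs["DZF"], 0.25 * rs["MZF"] + 0.02)
})

test_that("missingness reproduces the requested sub-sample overlap", {
  cfg <- small_biv_config(n = c(MZF = 600, DZF = 600))
  cfg$missingness <- c(hm_log = 0, swan_mi = 0.3)
  ds <- simulate_families(cfg, seed = 99)
  expect_equal(sum(is.na(ds$data$hm_log)), 0L)
  p_miss <- mean(is.na(ds$data$swan_mi))
  n <- nrow(ds$data)
  expect_lt(abs(p_miss - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("presets encode the documented structures", {
  hm <- preset("G-HM")
  SA <- hm$sigma_by_sex$F$A; SE <- hm$sigma_by_sex$F$E
  expect_equal(SA[1, 1] / (SA[1, 1] + SE[1, 1]), 0.40)
  expect_equal(hm$mean$beta["hm_log", "sex_male"], log(1.032))
  biv <- preset("G-BIV-MI")
  A <- biv$sigma_by_sex$F$A; E <- biv$sigma_by_sex$F$E
  rg <- A[1, 2] / sqrt(A[1, 1] * A[2, 2])
  re <- E[1, 2] / sqrt(E[1, 1] * E[2, 2])
  expect_equal(rg, 0.24, tolerance = 1e-12)
  expect_equal(re, 0.12, tolerance = 1e-12)
  P <- A + E
  expect_equal(P[1, 2] / sqrt(P[1, 1] * P[2, 2]), 0.178, tolerance = 5e-3)
  sl <- preset("G-SEXLIM-MH")
  fcov_mz <- sl$sigma_by_sex$F$A[1, 1] + sl$sigma_by_sex$F$C[1, 1]
  expect_equal(fcov_mz, 0.97)
  mcov_mz <- sl$sigma_by_sex$M$A[1, 1] + sl$sigma_by_sex$M$D[1, 1]
  expect_equal(mcov_mz, 0.64)
  mcov_dz <- 0.5 * sl$sigma_by_sex$M$A[1, 1] +
    0.25 * sl$sigma_by_sex$M$D[1, 1]
  expect_equal(mcov_dz, 0.27)
  # contrast-solved univariate preset matches the printed pair correlations
  mi <- preset("G-MI")
  ds <- simulate_families(mi, seed = 1)
  expect_s3_class(ds, "twin_dataset")
  expect_error(preset("nope"))
})

test_that("likert scoring discretises and attenuates", {
  expect_equal(simulate_likert_scores(-50, n_items = 9, levels = 5,
                                      item_sd = 0.5), -2)
  expect_equal(simulate_likert_scores(50, n_items = 9, levels = 7,
                                      item_sd = 0.5), 3)
  set.seed(7)
  lat <- rnorm(3000)
  s5 <- simulate_likert_scores(lat, n_items = 9, levels = 5, item_sd = 1.5)
  s7 <- simulate_likert_scores(lat, n_items = 9, levels = 7, item_sd = 1.5)
  expect_equal(mean(s5), 0, tolerance = 0.1)
  # more response levels retain more of the latent signal at matched noise
  expect_gt(cor(lat, s7), cor(lat, s5))
  expect_lt(cor(lat, s5), 1)
  expect_error(simulate_likert_scores(0, thresholds = c(1, 0.5, 2, 3)),
               "increasing")
})

test_that("motion-parameter simulation honours its controls", {
  z <- simulate_motion_params(drift_sd = 0, spike_prob = 0, seed = 1)
  expect_equal(max(abs(z$translations)), 0)
  expect_equal(mean(framewise_series(z)), 0)
  spiky <- simulate_motion_params(drift_sd = 0, spike_prob = 1,
                                  spike_scale = 8, seed = 2)
  expect_true(gross_motion_flag(spiky))
  a <- simulate_motion_params(seed = 5); b <- simulate_motion_params(seed = 5)
  expect_identical(a$translations, b$translations)
  c2 <- simulate_motion_params(seed = 6)
  expect_false(identical(a$translations, c2$translations))
})

test_that("dataset validation rejects inconsistent families", {
  d <- data.frame(family_id = c("f", "f"), individual_id = c("a", "b"),
                  zygosity = "MZF", sex = c("F", "M"), birth_order = 1:2,
                  hm_log = c(0, 0))
  expect_error(twin_dataset(d), "differ in sex")
  d2 <- d; d2$zygosity <- "DZOS"; d2$sex <- c("F", "F")
  expect_error(twin_dataset(d2), "share sex")
  d3 <- d; d3$sex <- c("F", "F"); d3$individual_id <- c("a", "a")
  expect_error(twin_dataset(d3), "unique")
})
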