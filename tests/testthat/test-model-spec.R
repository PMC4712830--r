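# Model specifications: biometrical relatedness expectations, implied pair
# moments (against direct substitution and a brute-force factor-score
# simulation), PSD invariants, and agreement between the generic and
# compiled covariance builders.

test_that("component correlations follow biometrical expectations", {
  expect_equal(component_correlation("A", "MZF"), 1)
  expect_equal(component_correlation("A", "MZM"), 1)
  expect_equal(component_correlation("A", "DZM"), 0.5)
  expect_equal(component_correlation("A", "SIB"), 0.5)
  expect_equal(component_correlation("D", "MZF"), 1)
  expect_equal(component_correlation("D", "DZM"), 0.25)
  expect_equal(component_correlation("C", "DZOS"), 1)
  expect_equal(component_correlation("E", "MZF"), 0)
  expect_equal(component_correlation("A", "DZOS", rg_mf = 1), 0.5)
  expect_equal(component_correlation("A", "DZOS", rg_mf = 0.6), 0.3)
})

test_that("spec constructors enforce the model-family rules", {
  expect_error(twin_model("t", components = c("A", "C", "D", "E")),
               "jointly identified")
  expect_error(twin_model("t", components = c("A", "C")), "mandatory")
  expect_error(twin_model(c("a", "b", "c"), parameterization = "share"),
               "at most 2")
  expect_error(twin_model(c("a", "b"), components = c("A", "C", "E"),
                          parameterization = "share_rp"), "bivariate AE")
})

test_that("implied pair moments reproduce direct substitution", {
  sp <- twin_model("t", c("A", "E"))
  par <- c(mu.t = 0, l.A.11 = sqrt(0.4), l.E.11 = sqrt(0.6))
  mz <- implied_pair_moments(sp, par, "MZF")
  expect_equal(mz$cov, matrix(c(1, 0.4, 0.4, 1), 2), tolerance = 1e-12)
  dz <- implied_pair_moments(sp, par, "DZM")
  expect_equal(dz$cov[1, 2], 0.2, tolerance = 1e-12)
  # ADE: DZ cross-covariance 0.5 a2 + 0.25 d2
  sp2 <- twin_model("t", c("A", "D", "E"))
  par2 <- c(mu.t = 0, l.A.11 = sqrt(0.3), l.D.11 = sqrt(0.4),
            l.E.11 = sqrt(0.3))
  dz2 <- implied_pair_moments(sp2, par2, "DZF")
  expect_equal(dz2$cov[1, 2], 0.5 * 0.3 + 0.25 * 0.4, tolerance = 1e-12)
  # mean model applies covariates per member
  sp3 <- twin_model("t", c("A", "E"), covariates = "sex_male")
  par3 <- c(mu.t = 1, b.t.sex_male = 0.5, l.A.11 = 0.6, l.E.11 = 0.8)
  os <- implied_pair_moments(sp3, par3, "DZOS",
                             covariates = list(list(sex_male = 0),
                                               list(sex_male = 1)))
  expect_equal(os$mean, c(1, 1.5))
})

test_that("ADE cross-covariance matches brute-force factor simulation", {
  set.seed(9)
  n <- 4e5
  a <- sqrt(0.3); d <- sqrt(0.4); e <- sqrt(0.3)
  # DZ pair: A correlated 0.5, D correlated 0.25, E independent
  a_c <- rnorm(n, 0, sqrt(0.5)); a1 <- a_c + rnorm(n, 0, sqrt(0.5))
  a2 <- a_c + rnorm(n, 0, sqrt(0.5))
  d_shared <- rnorm(n, 0, 0.5); d1 <- d_shared + rnorm(n, 0, sqrt(0.75))
  d2 <- d_shared + rnorm(n, 0, sqrt(0.75))
  y1 <- a * a1 + d * d1 + e * rnorm(n)
  y2 <- a * a2 + d * d2 + e * rnorm(n)
  sp <- twin_model("t", c("A", "D", "E"))
  par <- c(mu.t = 0, l.A.11 = a, l.D.11 = d, l.E.11 = e)
  expect_equal(cov(y1, y2), implied_pair_moments(sp, par, "DZF")$cov[1, 2],
               tolerance = 0.01)
})

test_that("implied covariance stays PSD over random parameter draws", {
  set.seed(3)
  specs <- list(
    twin_model(c("t1", "t2"), c("A", "E")),
    twin_model(c("t1", "t2"), c("A", "C", "E")),
    twin_model("t1", c("A", "D", "E"), contrast = TRUE),
    twin_model("t1", c("A", "E"), sex_limitation = "general",
               rg_mf_free = TRUE))
  groups <- c("MZF", "MZM", "DZF", "DZM", "DZOS")
  for (sp in specs) {
    for (rep in 1:20) {
      cl <- list(kind = "pair", group = "MZF", sexes = c("F", "F"),
                 mean_label = "MZF")
      tpl <- twinmotion:::par_template(sp, list(cl))
      par <- setNames(rnorm(length(tpl$names)), tpl$names)
      par[tpl$names[startsWith(tpl$names, "s.")]] <- runif(1, -0.9, 0.9)
      par[tpl$names[tpl$names == "rg_mf"]] <- runif(1, -1, 1)
      for (g in groups) {
        mom <- implied_pair_moments(sp, par, g)
        ev <- eigen(mom$cov, symmetric = TRUE, only.values = TRUE)$values
        expect_gte(min(ev), -1e-10)
      }
    }
  }
})

test_that("compiled covariance builder agrees with the generic one", {
  set.seed(11)
  make_classes <- function() {
    cls <- list(
      list(kind = "pair", group = "MZF", sexes = c("F", "F")),
      list(kind = "pair", group = "MZM", sexes = c("M", "M")),
      list(kind = "pair", group = "DZF", sexes = c("F", "F")),
      list(kind = "pair", group = "DZOS", sexes = c("F", "M")),
      list(kind = "single", group = "DZM", sexes = "M"))
    lapply(cls, function(cl) { cl$mean_label <- cl$group; cl })
  }
  specs <- list(
    twin_model("t1", c("A", "E"), parameterization = "share",
               scale_groups = "DZOS"),
    twin_model(c("t1", "t2"), c("A", "E"), parameterization = "share"),
    twin_model(c("t1", "t2"), c("A", "E"), parameterization = "share_rp"),
    twin_model(c("t1", "t2"), c("A", "C", "E")),
    twin_model("t1", c("A", "D", "E"), contrast = TRUE),
    twin_model("t1", c("A", "C", "E"), sex_limitation = "general",
               rg_mf_free = TRUE))
  for (sp in specs) {
    classes <- make_classes()
    tpl <- twinmotion:::par_template(sp, classes)
    cov_names <- tpl$names[-seq_len(tpl$n_mean)]
    plan <- twinmotion:::compile_sigma_plan(sp, classes, cov_names)
    for (rep in 1:10) {
      pc <- setNames(runif(length(cov_names), 0.1, 0.9), cov_names)
      if ("rg_mf" %in% cov_names) pc["rg_mf"] <- runif(1, -1, 1)
      gen <- twinmotion:::build_sigma_list(sp, as.list(pc), classes)
      fast <- twinmotion:::sigma_from_plan(plan, as.numeric(pc))
      expect_false(is.null(gen) != is.null(fast))
      if (is.null(gen)) next
      for (i in seq_along(classes))
        expect_equal(fast$S[[i]], gen$S[[i]], tolerance = 1e-12)
    }
  }
})

test_that("saturated classes map groups to shared parameters", {
  grp <- c("MZF", "MZM", "DZF", "DZM", "DZOS")
  cmap <- setNames(grp, grp); cmap[c("MZF", "MZM")] <- "MZ"
  sp <- saturated_model("t", cov_classes = cmap)
  par <- c(mu.t = 0, v.MZF = 1, v.MZM = 1.2, v.DZF = 1, v.DZM = 1,
           v.DZOS = 1, c.MZ = 0.5, c.DZF = 0.2, c.DZM = 0.2, c.DZOS = 0.1)
  m1 <- implied_pair_moments(sp, par, "MZF")
  m2 <- implied_pair_moments(sp, par, "MZM")
  expect_equal(m1$cov[1, 2], 0.5)
  expect_equal(m2$cov[1, 2], 0.5)
  expect_equal(m2$cov[1, 1], 1.2)
  # sibling pairs take the matching DZ class
  sib <- implied_pair_moments(sp, par, "SIB", sexes = c("F", "F"))
  expect_equal(sib$cov[1, 2], 0.2)
})
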