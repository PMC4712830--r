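# Hypothesis-test battery and the univariate / bivariate / sex-limitation
# analyses built on the FIML fitter.

sat_full_spec <- function(trait, covariates, birth_order = TRUE) {
  saturated_model(trait, covariates = covariates,
                  birth_order_mean = birth_order)
}

groups_present <- function(dataset) {
  fams <- split_families(dataset)
  grp <- vapply(fams, function(fam) {
    if (nrow(fam) == 2L) effective_group(fam$zygosity[1L], fam$sex)
    else NA_character_
  }, character(1))
  table(factor(grp[!is.na(grp)],
               c("MZF", "MZM", "DZF", "DZM", "DZOS")))
}

#' Homogeneity and covariate test battery
#'
#' Likelihood-ratio tests between the saturated model and its constrained
#' versions, mirroring the classical preliminary tests of a twin analysis:
#' birth-order mean effect, sex differences in mean/variance, quantitative
#' sex limitation (same-sex pair covariance equal across sexes), qualitative
#' sex limitation (opposite-sex pair covariance equal to same-sex DZ),
#' presence of genetic factors (MZ covariance equal to DZ covariance),
#' familial aggregation (all pair covariances null), and one test per mean
#' covariate. Tests whose groups are absent from the data are skipped with a
#' reason.
#'
#' @param dataset a [twin_dataset()].
#' @param trait trait column name.
#' @param covariates covariate columns screened in the mean model (default
#'   `sex_male` plus `age_scan` when present).
#' @param seed passed to [fit_model()].
#' @return data.frame with one row per test: `test`, `statistic`, `df`,
#'   `p`, `estimate` (covariate tests only), `note`.
#' @export
homogeneity_battery <- function(dataset, trait, covariates = NULL,
                                seed = 1L) {
  if (is.null(covariates))
    covariates <- intersect(c("sex_male", "age_scan"), names(dataset$data))
  gp <- groups_present(dataset)
  have_sexes <- gp[["MZF"]] > 2 && gp[["MZM"]] > 2 &&
    gp[["DZF"]] > 2 && gp[["DZM"]] > 2
  have_os <- gp[["DZOS"]] > 2

  grp <- c("MZF", "MZM", "DZF", "DZM", "DZOS")
  id_map <- setNames(grp, grp)
  full_spec <- sat_full_spec(trait, covariates)
  full <- fit_model(dataset, full_spec, seed = seed)

  rows <- list()
  push <- function(test, res, estimate = NA_real_, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test,
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      df = if (is.null(res)) NA_integer_ else res$df,
      p = if (is.null(res)) NA_real_ else res$p,
      estimate = estimate, note = note, stringsAsFactors = FALSE)
  }
  run_nested <- function(spec, fix = NULL)
    fit_model(dataset, spec, seed = seed, fix = fix)

  # birth order: drop the second-born mean offset
  nested <- run_nested(full_spec, fix = setNames(0, paste0("bo.", trait)))
  push("birth_order", lrt(full, nested, refit = list(dataset = dataset)))

  # sex groups: no sex mean effect, variances equal across sexes
  if (!"sex_male" %in% covariates) {
    push("sex_groups", NULL, note = "sex_male not among covariates")
  } else if (!have_sexes) {
    push("sex_groups", NULL, note = "both sexes not represented in MZ and DZ")
  } else {
    vmap <- id_map; vmap[c("MZF", "MZM")] <- "MZ"; vmap[c("DZF", "DZM")] <- "DZ"
    sp <- saturated_model(trait, covariates = covariates,
                          var_classes = vmap, birth_order_mean = TRUE)
    nested <- run_nested(sp, fix = setNames(0, paste0("b.", trait, ".sex_male")))
    push("sex_groups", lrt(full, nested, refit = list(dataset = dataset)))
  }

  # quantitative sex limitation: same-sex pair covariances equal across sexes
  if (!have_sexes) {
    push("quantitative_sex_limitation", NULL,
         note = "both sexes not represented in MZ and DZ")
  } else {
    cmap <- id_map; cmap[c("MZF", "MZM")] <- "MZ"; cmap[c("DZF", "DZM")] <- "DZ"
    sp <- saturated_model(trait, covariates = covariates, cov_classes = cmap,
                          birth_order_mean = TRUE)
    push("quantitative_sex_limitation",
         lrt(full, run_nested(sp), refit = list(dataset = dataset)))
  }

  # qualitative sex limitation: DZOS covariance equal to same-sex DZ
  if (!have_os) {
    push("qualitative_sex_limitation", NULL, note = "no opposite-sex pairs")
  } else {
    cmap_full <- id_map; cmap_full[c("DZF", "DZM")] <- "DZ"
    sp_full <- saturated_model(trait, covariates = covariates,
                               cov_classes = cmap_full,
                               birth_order_mean = TRUE)
    cmap_null <- cmap_full; cmap_null["DZOS"] <- "DZ"
    sp_null <- saturated_model(trait, covariates = covariates,
                               cov_classes = cmap_null,
                               birth_order_mean = TRUE)
    push("qualitative_sex_limitation",
         lrt(run_nested(sp_full), run_nested(sp_null),
             refit = list(dataset = dataset)))
  }

  # presence of genetic factors: pair covariance equal across zygosity
  cmap_mzdz <- id_map; cmap_mzdz[c("MZF", "MZM")] <- "MZ"
  cmap_mzdz[c("DZF", "DZM", "DZOS")] <- "DZ"
  sp_full <- saturated_model(trait, covariates = covariates,
                             cov_classes = cmap_mzdz, birth_order_mean = TRUE)
  fit_mzdz <- run_nested(sp_full)
  cmap_one <- id_map; cmap_one[grp] <- "ALL"
  sp_one <- saturated_model(trait, covariates = covariates,
                            cov_classes = cmap_one, birth_order_mean = TRUE)
  fit_one <- run_nested(sp_one)
  push("presence_genetic_factors",
       lrt(fit_mzdz, fit_one, refit = list(dataset = dataset)))

  # familial aggregation: pair covariance null
  cmap_zero <- id_map; cmap_zero[grp] <- "zero"
  sp_zero <- saturated_model(trait, covariates = covariates,
                             cov_classes = cmap_zero, birth_order_mean = TRUE)
  push("familial_aggregation",
       lrt(fit_one, run_nested(sp_zero), refit = list(dataset = dataset)))

  # covariate effects
  for (cv in covariates) {
    pname <- paste0("b.", trait, ".", cv)
    nested <- run_nested(full_spec, fix = setNames(0, pname))
    push(paste0("covariate_", cv),
         lrt(full, nested, refit = list(dataset = dataset)),
         estimate = unname(full$estimates[pname]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Twin pair correlation
#'
#' Cross-member correlation of one trait within a zygosity group, either
#' from the per-group saturated ML fit (`method = "ml"`, the default, which
#' respects covariate adjustment and FIML missingness handling) or as the
#' double-entered Pearson correlation of complete pairs.
#'
#' @param dataset a [twin_dataset()].
#' @param trait trait column name.
#' @param group `"MZ"`, `"DZ"` or a specific label (`MZF`, `DZOS`, ...).
#' @param method `"ml"` or `"pearson"`.
#' @param covariates mean-model covariates for the ML method.
#' @param seed passed to [fit_model()].
#' @return correlation in [-1, 1].
#' @export
pair_correlation <- function(dataset, trait, group,
                             method = c("ml", "pearson"),
                             covariates = character(0), seed = 1L) {
  method <- match.arg(method)
  labels <- switch(group,
    MZ = c("MZF", "MZM"), DZ = c("DZF", "DZM", "DZOS"),
    group)
  fams <- split_families(dataset)
  keep <- Filter(function(fam) {
    nrow(fam) == 2L &&
      effective_group(fam$zygosity[1L], fam$sex) %in% labels
  }, fams)
  if (!length(keep)) stop("no complete pairs in group ", group)
  sub <- twin_dataset(do.call(rbind, keep), traits = dataset$traits)
  pairs <- do.call(rbind, lapply(keep, function(fam) {
    y <- fam[[trait]]
    if (anyNA(y)) return(NULL)
    y
  }))
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("fewer than 3 complete pairs in group ", group)
  if (method == "pearson") {
    de <- rbind(pairs, pairs[, 2:1, drop = FALSE])
    return(max(-1, min(1, cor(de[, 1L], de[, 2L]))))
  }
  grp <- c("MZF", "MZM", "DZF", "DZM", "DZOS")
  one <- setNames(rep("G", 5L), grp)
  sp <- saturated_model(trait, covariates = covariates,
                        var_classes = one, cov_classes = one)
  fit <- fit_model(sub, sp, seed = seed)
  v <- fit$estimates[["v.G"]]; cc <- fit$estimates[["c.G"]]
  max(-1, min(1, cc / v))
}

#' Univariate heritability analysis with model selection
#'
#' Fits a chain of nested univariate models and selects the most
#' parsimonious one that is not significantly worse by LRT at `alpha`:
#' `ACE -> AE -> E` (or `ADE -> AE -> E` when the pair correlations suggest
#' dominance, i.e. rMZ > 2 rDZ, or when `components` is given). Standardised
#' shares are reported with profile-likelihood CIs for the selected model's
#' A share.
#'
#' @param dataset a [twin_dataset()].
#' @param trait trait column name.
#' @param covariates mean-model covariates.
#' @param components optional starting set, e.g. `c("A","D","E")`.
#' @param alpha selection level (default 0.05).
#' @param scale_groups passed to [twin_model()].
#' @param ci compute the profile CI of the selected model's heritability.
#' @param seed passed to [fit_model()].
#' @return list with `fits` (named list of `twin_fit`), `tests` (LRT table),
#'   `selected` (model name), `h2`, `h2_ci`.
#' @export
heritability_analysis <- function(dataset, trait, covariates = character(0),
                                  components = NULL, alpha = 0.05,
                                  scale_groups = character(0), ci = TRUE,
                                  seed = 1L) {
  if (is.null(components)) {
    rmz <- tryCatch(pair_correlation(dataset, trait, "MZ", "pearson"),
                    error = function(e) NA)
    rdz <- tryCatch(pair_correlation(dataset, trait, "DZ", "pearson"),
                    error = function(e) NA)
    components <- if (is.finite(rmz) && is.finite(rdz) && rmz > 2 * rdz)
      c("A", "D", "E") else c("A", "C", "E")
  }
  mk <- function(comps) twin_model(trait, components = comps,
                                   covariates = covariates,
                                   parameterization = "share",
                                   scale_groups = scale_groups)
  chain <- list()
  chain[[paste(components, collapse = "")]] <- mk(components)
  chain[["AE"]] <- mk(c("A", "E"))
  chain[["E"]] <- mk("E")
  fits <- lapply(chain, function(sp) fit_model(dataset, sp, seed = seed))
  tests <- list()
  selected <- names(chain)[1L]
  for (k in seq_len(length(chain) - 1L)) {
    res <- lrt(fits[[k]], fits[[k + 1L]], refit = list(dataset = dataset))
    tests[[length(tests) + 1L]] <- data.frame(
      full = names(chain)[k], nested = names(chain)[k + 1L],
      statistic = res$statistic, df = res$df, p = res$p)
    if (selected == names(chain)[k] && res$p > alpha)
      selected <- names(chain)[k + 1L]
  }
  sel_fit <- fits[[selected]]
  h2 <- if (selected == "E") 0 else
    unname(sel_fit$estimates[[paste0("sh.A.", trait)]])
  h2_ci <- NULL
  if (ci && selected != "E") {
    h2_ci <- profile_ci(dataset, chain[[selected]], sel_fit,
                        paste0("sh.A.", trait))
  }
  list(fits = fits, tests = do.call(rbind, tests), selected = selected,
       h2 = h2, h2_ci = h2_ci)
}

#' General sex-limitation analysis
#'
#' Fits the general sex-limitation model (sex-specific path sets plus a
#' cross-sex genetic correlation identified by the opposite-sex pairs) and
#' compares it to the standard two-group model by LRT. Without opposite-sex
#' pairs the cross-sex correlation is unidentified and fixed to 1 with a
#' warning. When the free cross-sex correlation converges to the boundary
#' (|rg_mf| ~ 1) it is re-fixed at 1, which leaves the fit unchanged, and
#' flagged.
#'
#' @param dataset a [twin_dataset()].
#' @param trait trait column name.
#' @param components component set of the general model (default ACE, the
#'   "A, C and E free per sex" form).
#' @param covariates mean-model covariates.
#' @param rg_mf_free estimate the cross-sex genetic correlation.
#' @param seed passed to [fit_model()].
#' @return list with `general` and `standard` fits, `test` (LRT),
#'   `by_sex` standardised shares, `implied_cov` per-sex MZ/DZ implied
#'   cross-twin covariances, `rg_mf`, `rg_mf_at_bound`.
#' @export
sex_limitation_analysis <- function(dataset, trait,
                                    components = c("A", "C", "E"),
                                    covariates = character(0),
                                    rg_mf_free = FALSE, seed = 1L) {
  gp <- groups_present(dataset)
  if (gp[["DZOS"]] == 0 && rg_mf_free) {
    warning("no opposite-sex pairs: cross-sex genetic correlation fixed to 1")
    rg_mf_free <- FALSE
  }
  gen_spec <- twin_model(trait, components = components,
                         covariates = covariates,
                         sex_limitation = "general",
                         rg_mf_free = rg_mf_free)
  gen <- fit_model(dataset, gen_spec, seed = seed)
  rg_mf <- if (rg_mf_free) unname(gen$estimates[["rg_mf"]]) else 1
  at_bound <- rg_mf_free && abs(abs(rg_mf) - 1) < 1e-3
  if (at_bound) {
    gen_fixed <- fit_model(dataset, gen_spec, seed = seed,
                           fix = c(rg_mf = sign(rg_mf)))
    if (gen_fixed$minus2lnL <= gen$minus2lnL + 1e-6) gen <- gen_fixed
  }
  std_spec <- twin_model(trait, components = components,
                         covariates = covariates)
  std <- fit_model(dataset, std_spec, seed = seed)
  test <- lrt(gen, std, refit = list(dataset = dataset))
  par <- as.list(gen$estimates)
  cs <- component_sigmas(gen_spec, par)
  implied <- lapply(c(F = "F", M = "M"), function(sx) {
    grp <- if (sx == "F") c(MZ = "MZF", DZ = "DZF") else c(MZ = "MZM", DZ = "DZM")
    vapply(grp, function(g) {
      sum(vapply(components, function(X)
        component_correlation(X, g) * cs[[sx]][[X]]$S[1L, 1L], numeric(1)))
    }, numeric(1))
  })
  list(general = gen, standard = std, test = test,
       by_sex = gen$standardized$shares, implied_cov = implied,
       rg_mf = rg_mf, rg_mf_at_bound = at_bound)
}

#' Bivariate genetic/environmental correlation analysis
#'
#' Fits the bivariate AE Cholesky-equivalent model (share parameterization)
#' with the given mean covariates and returns the phenotypic, genetic and
#' environmental correlations with profile-likelihood CIs and LRT p-values
#' from dropping the corresponding cross path (df = 1 each). Optionally also
#' returns the LRT for adding a block of extra covariates (df = number of
#' extra covariates x 2 traits).
#'
#' @param dataset a [twin_dataset()].
#' @param trait_pair character vector of 2 trait column names.
#' @param covariates mean-model covariates of the base model.
#' @param extra_covariates covariates whose joint addition is tested.
#' @param ci compute profile CIs (slower).
#' @param seed passed to [fit_model()].
#' @return list with `fit`, `rp`, `rg`, `re`, `ci` (named list), `tests`
#'   (LRT p-values for rg = 0, re = 0, rp = 0), `covariate_test`.
#' @export
cross_trait_analysis <- function(dataset, trait_pair,
                                 covariates = c("sex_male", "age_scan"),
                                 extra_covariates = character(0),
                                 ci = TRUE, seed = 1L) {
  stopifnot(length(trait_pair) == 2L)
  spec <- twin_model(trait_pair, components = c("A", "E"),
                     covariates = covariates, parameterization = "share")
  fit <- fit_model(dataset, spec, seed = seed)
  st <- fit$standardized
  tests <- list()
  fit_rg0 <- fit_model(dataset, spec, seed = seed, fix = c(r.A = 0))
  tests$rg <- lrt(fit, fit_rg0, refit = list(dataset = dataset))
  fit_re0 <- fit_model(dataset, spec, seed = seed, fix = c(r.E = 0))
  tests$re <- lrt(fit, fit_re0, refit = list(dataset = dataset))
  spec_rp <- twin_model(trait_pair, components = c("A", "E"),
                        covariates = covariates,
                        parameterization = "share_rp")
  fit_rp <- fit_model(dataset, spec_rp, seed = seed)
  fit_rp0 <- fit_model(dataset, spec_rp, seed = seed, fix = c(rp = 0))
  tests$rp <- lrt(fit_rp, fit_rp0, refit = list(dataset = dataset))
  cis <- NULL
  if (ci) {
    cis <- list(
      rg = profile_ci(dataset, spec, fit, "r.A"),
      re = profile_ci(dataset, spec, fit, "r.E"),
      rp = profile_ci(dataset, spec_rp, fit_rp, "rp"))
  }
  covariate_test <- NULL
  if (length(extra_covariates)) {
    spec_ext <- twin_model(trait_pair, components = c("A", "E"),
                           covariates = c(covariates, extra_covariates),
                           parameterization = "share")
    fit_ext <- fit_model(dataset, spec_ext, seed = seed)
    covariate_test <- lrt(fit_ext, fit, refit = list(dataset = dataset))
  }
  list(fit = fit, rp = st$rp, rg = st$rg, re = st$re, ci = cis,
       tests = tests, covariate_test = covariate_test)
}

#' Two-stage covariate residualisation helper
#'
#' Regresses significant covariates out of a trait by ordinary least squares
#' and returns a dataset whose trait column holds the residuals (plus the
#' original intercept). Covariate adjustment inside the likelihood is the
#' default analysis path; this helper exists for exact-replication workflows
#' that pre-residualise.
#'
#' @param dataset a [twin_dataset()].
#' @param trait trait column name.
#' @param covariates covariate columns to regress out.
#' @return a [twin_dataset()] with the trait replaced by residuals.
#' @export
residualize_trait <- function(dataset, trait, covariates) {
  d <- dataset$data
  f <- stats::as.formula(paste(trait, "~", paste(covariates, collapse = "+")))
  m <- stats::lm(f, data = d, na.action = stats::na.exclude)
  d[[trait]] <- as.numeric(stats::residuals(m)) + mean(d[[trait]], na.rm = TRUE)
  twin_dataset(d, traits = dataset$traits)
}
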