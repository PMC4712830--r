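# Synthetic twin-cohort generator: the variance-component model run
# forward, with cohort structure (group sizes, sex ratios, ages, raters)
# emulating a young-adult twin imaging sample.

#' Construct a generating configuration
#'
#' Full generative specification for a synthetic cohort: group sizes,
#' per-component covariance matrices (optionally sex-specific), mean model,
#' contrast paths, missingness and covariate distributions. Presets encoding
#' published summary statistics are available via [preset()].
#'
#' @param traits character vector of trait column names (subset of
#'   `hm_log, swan_mi, swan_mh, swan_si, swan_sh`).
#' @param n_pairs named integer vector over
#'   `MZF, MZM, DZF, DZM, DZOS, SIB` (missing entries default to 0).
#' @param n_singletons number of unpaired individuals.
#' @param sigma list of p x p component covariance matrices named among
#'   `A, C, D, E` (`E` required), or NULL when `sigma_by_sex` is given.
#' @param sigma_by_sex list with elements `F` and `M`, each a `sigma`-style
#'   list, for sex-limited generation.
#' @param rg_mf cross-sex genetic correlation applied to the A component of
#'   opposite-sex pairs.
#' @param mean list with `intercept` (named by trait; the expected value for
#'   a female at the covariate centres) and `beta` (traits x covariates
#'   matrix; covariates among `sex_male`, `age_scan`, `n_siblings`; the
#'   continuous ones act relative to their centres: age 22, siblings 3).
#' @param contrast numeric vector of reciprocal sibling-contrast paths per
#'   trait (default 0).
#' @param missingness named per-trait probability that an individual's value
#'   is unobserved (emulates overlapping rater sub-samples).
#' @param p_female sex ratio used for SIB pairs and singletons.
#' @param likert optional item-level discretisation, see
#'   [simulate_likert_scores()]: list with per-trait `levels` (5 or 7),
#'   `n_items`, `item_sd`.
#' @param name label carried through to outputs.
#' @return An object of class `generating_config`.
#' @export
generating_config <- function(traits, n_pairs, n_singletons = 0L,
                              sigma = NULL, sigma_by_sex = NULL, rg_mf = 1,
                              mean = NULL, contrast = NULL,
                              missingness = NULL, p_female = 0.64,
                              likert = NULL, name = "custom") {
  p <- length(traits)
  np <- setNames(rep(0L, 6L), ZYGOSITY_GROUPS)
  np[names(n_pairs)] <- as.integer(n_pairs)
  if (any(np < 0) || n_singletons < 0) stop("counts must be >= 0")
  if (is.null(sigma_by_sex)) {
    if (is.null(sigma)) stop("either sigma or sigma_by_sex is required")
    sigma_by_sex <- list(F = sigma, M = sigma)
  }
  for (sx in c("F", "M")) {
    s <- sigma_by_sex[[sx]]
    if (!"E" %in% names(s)) stop("sigma must include an E component")
    for (X in names(s)) {
      m <- as.matrix(s[[X]])
      if (!all(dim(m) == p)) stop("sigma ", X, " must be ", p, "x", p)
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) stop("sigma ", X, " (", sx, ") is not PSD")
      sigma_by_sex[[sx]][[X]] <- m
    }
  }
  if (is.null(contrast)) contrast <- rep(0, p)
  if (any(abs(contrast) >= 1)) stop("|contrast| must be < 1")
  miss <- setNames(rep(0, p), traits)
  if (!is.null(missingness)) miss[names(missingness)] <- missingness
  if (any(miss < 0 | miss > 1)) stop("missingness probabilities in [0,1]")
  if (is.null(mean))
    mean <- list(intercept = setNames(rep(0, p), traits),
                 beta = matrix(0, p, 0, dimnames = list(traits, NULL)))
  structure(
    list(name = name, traits = traits, n_pairs = np,
         n_singletons = as.integer(n_singletons),
         sigma_by_sex = sigma_by_sex, rg_mf = rg_mf, mean = mean,
         contrast = contrast, missingness = miss, p_female = p_female,
         likert = likert),
    class = "generating_config")
}

#' @export
print.generating_config <- function(x, ...) {
  cat(sprintf("<generating_config> %s: traits %s\n", x$name,
              paste(x$traits, collapse = ", ")))
  cat("  pairs:", paste(sprintf("%s=%d", names(x$n_pairs), x$n_pairs),
                        collapse = " "),
      sprintf(" singletons=%d\n", x$n_singletons))
  invisible(x)
}

COVARIATE_CENTERS <- c(sex_male = 0, age_scan = 22, n_siblings = 3)

# Solve dominance-plus-contrast structure matching target MZ/DZ pair
# correlations: with latent variance v, pair covariance c and contrast s the
# observed correlation is (c (1+s^2) + 2 s v) / (v (1+s^2) + 2 s c).
solve_contrast_d <- function(r_mz, r_dz) {
  fn <- function(par) {
    d2 <- par[1L]; s <- par[2L]
    rob <- function(cc) (cc * (1 + s^2) + 2 * s) / ((1 + s^2) + 2 * s * cc)
    (rob(d2) - r_mz)^2 + (rob(0.25 * d2) - r_dz)^2
  }
  res <- optim(c(0.5, -0.05), fn, method = "L-BFGS-B",
               lower = c(0.01, -0.5), upper = c(0.99, 0.5),
               control = list(factr = 1e4))
  if (res$value > 1e-8)
    warning("contrast preset solve residual ", format(res$value))
  c(d2 = res$par[1L], s = res$par[2L])
}

hm_sigma <- function() list(A = matrix(0.40 * 0.1225),
                            E = matrix(0.60 * 0.1225))

biv_sigma <- function(h2, v2, rg, re) {
  # trait 1 is log head motion (h2 = 0.40, var = 0.35^2)
  a2 <- c(0.40 * 0.1225, h2 * v2)
  e2 <- c(0.60 * 0.1225, (1 - h2) * v2)
  A <- diag(a2); A[1L, 2L] <- A[2L, 1L] <- rg * sqrt(a2[1L] * a2[2L])
  E <- diag(e2); E[1L, 2L] <- E[2L, 1L] <- re * sqrt(e2[1L] * e2[2L])
  list(A = A, E = E)
}

hm_mean <- function() list(
  intercept = c(hm_log = -2.62),
  beta = matrix(c(log(1.032), log(0.994)), 1L, 2L,
                dimnames = list("hm_log", c("sex_male", "age_scan"))))

biv_mean <- function(trait, female_mean, sex_diff) {
  b <- rbind(c(log(1.032), log(0.994)), c(sex_diff, 0))
  dimnames(b) <- list(c("hm_log", trait), c("sex_male", "age_scan"))
  list(intercept = setNames(c(-2.62, female_mean), c("hm_log", trait)),
       beta = b)
}

maternal_pairs <- c(MZF = 61, MZM = 34, DZF = 60, DZM = 33, DZOS = 51,
                    SIB = 22)
self_pairs <- c(MZF = 59, MZM = 42, DZF = 64, DZM = 36, DZOS = 56, SIB = 22)
combined_pairs <- c(MZF = 125, MZM = 71, DZF = 112, DZM = 62, DZOS = 104,
                    SIB = 22)

#' Named generating presets
#'
#' Ready-made configurations whose implied moments encode published summary
#' statistics for this cohort design:
#' \describe{
#'   \item{G-HM}{univariate AE for log head motion, h2 = 0.40, total SD
#'     0.35, male offset +3.2% and -0.6%/year age effect on the raw scale,
#'     combined-sample group sizes.}
#'   \item{G-MI, G-MH}{univariate maternal Inattention /
#'     Hyperactivity-Impulsivity matching MZ/DZ pair correlations 0.72/0.15
#'     (dominance plus a negative contrast path) and 0.86/0.51 (ACE).}
#'   \item{G-SI}{bivariate head motion x self-report Inattention, rg = 0.19,
#'     re = 0.07, self-report sub-sample sizes.}
#'   \item{G-SH}{bivariate head motion x self-report
#'     Hyperactivity-Impulsivity, rg = 0.40, re = 0.03 (implied rp 0.12),
#'     self-report sub-sample sizes.}
#'   \item{G-BIV-MI}{bivariate head motion x maternal Inattention, rg =
#'     0.24, re = 0.12, h2 = (0.40, 0.72) (implied rp 0.178), maternal
#'     sub-sample sizes.}
#'   \item{G-BIV-MH}{bivariate head motion x maternal
#'     Hyperactivity-Impulsivity, rg = 0.23, re = 0.05, h2 = (0.40, 0.86).}
#'   \item{G-SEXLIM-MH}{maternal Hyperactivity-Impulsivity with sex-specific
#'     components implying female MZ/DZ pair covariances 0.97/0.74 (ACE) and
#'     male 0.64/0.27 (ADE), cross-sex genetic correlation 1.}
#' }
#'
#' @param name preset name.
#' @return a [generating_config()].
#' @export
preset <- function(name = c("G-HM", "G-MI", "G-MH", "G-SI", "G-SH",
                            "G-BIV-MI", "G-BIV-MH", "G-SEXLIM-MH")) {
  name <- match.arg(name)
  switch(name,
    "G-HM" = generating_config(
      "hm_log", combined_pairs, n_singletons = 57L, sigma = hm_sigma(),
      mean = hm_mean(), p_female = 0.64, name = name),
    "G-MI" = {
      v <- 1.14^2
      ds <- solve_contrast_d(0.72, 0.15)
      generating_config(
        "swan_mi", maternal_pairs, n_singletons = 149L,
        sigma = list(D = matrix(ds[["d2"]] * v),
                     E = matrix((1 - ds[["d2"]]) * v)),
        contrast = ds[["s"]],
        mean = list(intercept = c(swan_mi = -1.24),
                    beta = matrix(0.54, 1L, 1L,
                                  dimnames = list("swan_mi", "sex_male"))),
        p_female = 0.64, name = name)
    },
    "G-MH" = {
      v <- 1.10^2
      generating_config(
        "swan_mh", maternal_pairs, n_singletons = 149L,
        sigma = list(A = matrix(0.70 * v), C = matrix(0.16 * v),
                     E = matrix(0.14 * v)),
        mean = list(intercept = c(swan_mh = -1.21),
                    beta = matrix(0.40, 1L, 1L,
                                  dimnames = list("swan_mh", "sex_male"))),
        p_female = 0.64, name = name)
    },
    "G-SI" = generating_config(
      c("hm_log", "swan_si"), self_pairs, n_singletons = 211L,
      sigma = biv_sigma(h2 = 0.12, v2 = 0.59^2, rg = 0.19, re = 0.07),
      mean = biv_mean("swan_si", -0.57, 0.17), p_female = 0.58,
      name = name),
    "G-SH" = generating_config(
      c("hm_log", "swan_sh"), self_pairs, n_singletons = 211L,
      sigma = biv_sigma(h2 = 0.16, v2 = 0.62^2, rg = 0.40, re = 0.03),
      mean = biv_mean("swan_sh", -0.57, 0.21), p_female = 0.58,
      name = name),
    "G-BIV-MI" = generating_config(
      c("hm_log", "swan_mi"), maternal_pairs, n_singletons = 149L,
      sigma = biv_sigma(h2 = 0.72, v2 = 1.14^2, rg = 0.24, re = 0.12),
      mean = biv_mean("swan_mi", -1.24, 0.54), p_female = 0.64,
      name = name),
    "G-BIV-MH" = generating_config(
      c("hm_log", "swan_mh"), maternal_pairs, n_singletons = 149L,
      sigma = biv_sigma(h2 = 0.86, v2 = 1.10^2, rg = 0.23, re = 0.05),
      mean = biv_mean("swan_mh", -1.21, 0.40), p_female = 0.64,
      name = name),
    "G-SEXLIM-MH" = {
      vF <- 1.07^2; vM <- 1.10^2
      generating_config(
        "swan_mh", maternal_pairs, n_singletons = 149L,
        sigma_by_sex = list(
          F = list(A = matrix(0.46), C = matrix(0.51), D = matrix(0),
                   E = matrix(vF - 0.97)),
          M = list(A = matrix(0.44), C = matrix(0), D = matrix(0.20),
                   E = matrix(vM - 0.64))),
        rg_mf = 1,
        mean = list(intercept = c(swan_mh = -1.21),
                    beta = matrix(0.40, 1L, 1L,
                                  dimnames = list("swan_mh", "sex_male"))),
        p_female = 0.64, name = name)
    })
}

rtnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# Joint component scores for a pair: member blocks L1 u and
# L2 (rho u + sqrt(1-rho^2) w) have the required within/cross covariances;
# rho = 1 with identical factors shares the score exactly.
draw_pair_component <- function(L1, L2, rho, p) {
  u <- rnorm(p)
  w <- rnorm(p)
  z1 <- L1 %*% u
  z2 <- L2 %*% (rho * u + sqrt(max(0, 1 - rho^2)) * w)
  cbind(as.numeric(z1), as.numeric(z2))
}

#' Simulate a twin cohort
#'
#' Draws per-family component scores (A shared exactly for MZ pairs,
#' correlated 0.5 for DZ/sibling pairs — times the cross-sex genetic
#' correlation for opposite-sex pairs — D correlated 1/0.25, C shared, E
#' independent), maps them through the component covariance structure,
#' applies the reciprocal contrast transform and the covariate mean model,
#' then applies missingness. Deterministic given `seed`.
#'
#' @param config a [generating_config()].
#' @param seed integer seed.
#' @return a [twin_dataset()].
#' @export
simulate_families <- function(config, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  traits <- config$traits
  p <- length(traits)
  chol_by_sex <- lapply(config$sigma_by_sex, function(s)
    lapply(s, chol_psd))
  comps <- names(config$sigma_by_sex$F)
  s <- config$contrast
  G <- if (any(s != 0)) {
    B <- matrix(0, 2L * p, 2L * p)
    for (t in seq_len(p)) { B[t, p + t] <- s[t]; B[p + t, t] <- s[t] }
    solve(diag(2L * p) - B)
  } else NULL

  n_total <- 2L * sum(config$n_pairs) + config$n_singletons
  col <- list(
    family_id = character(n_total), individual_id = character(n_total),
    zygosity = character(n_total), sex = character(n_total),
    birth_order = integer(n_total), age_scan = numeric(n_total),
    age_mother_report = numeric(n_total),
    age_self_report = numeric(n_total),
    wave_mother = integer(n_total), wave_self = integer(n_total),
    design_mother = character(n_total), design_self = character(n_total),
    n_siblings = integer(n_total))
  for (tr in TRAIT_COLUMNS) col[[tr]] <- rep(NA_real_, n_total)
  row_i <- 0L
  fam_counter <- 0L
  add_individual <- function(fid, iid, zyg, sex, bo, age_scan, n_sib,
                             values) {
    row_i <<- row_i + 1L
    i <- row_i
    col$family_id[i] <<- fid; col$individual_id[i] <<- iid
    col$zygosity[i] <<- zyg; col$sex[i] <<- sex
    col$birth_order[i] <<- bo; col$age_scan[i] <<- age_scan
    col$age_mother_report[i] <<- age_scan + rtnorm(1L, 1.2, 0.8, 0.01, 3.9)
    col$age_self_report[i] <<- age_scan + rtnorm(1L, 3.1, 1.5, 0.02, 7.1)
    col$wave_mother[i] <<- sample(1:2, 1L, prob = c(0.65, 0.35))
    col$wave_self[i] <<- sample(1:3, 1L, prob = c(0.2, 0.3, 0.5))
    col$design_mother[i] <<- sample(c("prospective", "retrospective"), 1L,
                                    prob = c(0.65, 0.35))
    col$design_self[i] <<- "prospective"
    col$n_siblings[i] <<- n_sib
    for (t in seq_len(p)) col[[traits[t]]][i] <<- values[t]
  }

  mean_for <- function(sex, age_scan, n_sib) {
    mu <- as.numeric(config$mean$intercept[traits])
    b <- config$mean$beta
    for (cv in colnames(b)) {
      x <- switch(cv, sex_male = as.numeric(sex == "M"),
                  age_scan = age_scan - COVARIATE_CENTERS[["age_scan"]],
                  n_siblings = n_sib - COVARIATE_CENTERS[["n_siblings"]],
                  stop("unsupported generator covariate ", cv))
      mu <- mu + b[traits, cv] * x
    }
    mu
  }

  pair_sexes <- function(zyg) switch(zyg,
    MZF = c("F", "F"), DZF = c("F", "F"),
    MZM = c("M", "M"), DZM = c("M", "M"),
    DZOS = c("F", "M"),
    SIB = sample(c("F", "M"), 2L, replace = TRUE,
                 prob = c(config$p_female, 1 - config$p_female)))

  for (zyg in ZYGOSITY_GROUPS) {
    for (k in seq_len(config$n_pairs[[zyg]])) {
      fam_counter <- fam_counter + 1L
      fid <- sprintf("F%04d", fam_counter)
      sexes <- pair_sexes(zyg)
      grp <- effective_group(zyg, sexes)
      age_scan <- rtnorm(1L, 22, 3, 18, 32)
      n_sib <- min(7L, 2L + rpois(1L, 1))
      dev <- matrix(0, p, 2L)
      for (X in comps) {
        rho <- component_correlation(X, grp, rg_mf = config$rg_mf)
        z <- draw_pair_component(chol_by_sex[[sexes[1L]]][[X]],
                                 chol_by_sex[[sexes[2L]]][[X]], rho, p)
        dev <- dev + z
      }
      m1 <- mean_for(sexes[1L], age_scan, n_sib)
      m2 <- mean_for(sexes[2L], age_scan, n_sib)
      y <- c(m1 + dev[, 1L], m2 + dev[, 2L])
      if (!is.null(G)) y <- as.numeric(G %*% y)
      y1 <- y[seq_len(p)]; y2 <- y[p + seq_len(p)]
      if (!is.null(config$likert)) {
        y1 <- apply_likert(y1, traits, config$likert)
        y2 <- apply_likert(y2, traits, config$likert)
      }
      add_individual(fid, paste0(fid, "_1"), zyg, sexes[1L], 1L, age_scan,
                     n_sib, y1)
      add_individual(fid, paste0(fid, "_2"), zyg, sexes[2L], 2L, age_scan,
                     n_sib, y2)
    }
  }
  # singletons: unpaired individuals, zygosity label sampled from the pair
  # composition, only means/variances identified
  if (config$n_singletons > 0L) {
    wts <- config$n_pairs + 1e-9
    for (k in seq_len(config$n_singletons)) {
      fam_counter <- fam_counter + 1L
      fid <- sprintf("F%04d", fam_counter)
      sex <- sample(c("F", "M"), 1L,
                    prob = c(config$p_female, 1 - config$p_female))
      zyg <- sample(ZYGOSITY_GROUPS, 1L, prob = wts)
      if (zyg %in% c("MZF", "DZF") && sex == "M") zyg <- sub("F$", "M", zyg)
      if (zyg %in% c("MZM", "DZM") && sex == "F") zyg <- sub("M$", "F", zyg)
      age_scan <- rtnorm(1L, 22, 3, 18, 32)
      n_sib <- min(7L, 2L + rpois(1L, 1))
      dev <- numeric(p)
      for (X in comps) dev <- dev +
        as.numeric(chol_by_sex[[sex]][[X]] %*% rnorm(p))
      yv <- mean_for(sex, age_scan, n_sib) + dev
      if (!is.null(config$likert)) yv <- apply_likert(yv, traits, config$likert)
      add_individual(fid, paste0(fid, "_1"), zyg, sex, 1L, age_scan, n_sib,
                     yv)
    }
  }
  d <- as.data.frame(col, stringsAsFactors = FALSE)
  # missingness
  for (t in seq_len(p)) {
    pr <- config$missingness[[traits[t]]]
    if (pr > 0) {
      drop <- runif(nrow(d)) < pr
      d[[traits[t]]][drop] <- NA_real_
    }
  }
  twin_dataset(d, traits = traits)
}

apply_likert <- function(values, traits, likert) {
  for (t in seq_along(traits)) {
    cfg <- likert[[traits[t]]]
    if (is.null(cfg)) next
    values[t] <- simulate_likert_scores(values[t],
                                        n_items = cfg$n_items,
                                        levels = cfg$levels,
                                        item_sd = cfg$item_sd)
  }
  values
}

#' Discretise a latent score through Likert-type items
#'
#' Each of `n_items` items adds independent normal noise to the latent value
#' and cuts the result at the thresholds into integer codes centred at 0
#' (`-(levels-1)/2 ... +(levels-1)/2`); the scale score is the item mean.
#' This attenuates reliability relative to the latent value (more for 5-level
#' self report than 7-level informant report at matched noise).
#'
#' @param latent numeric vector of latent trait values.
#' @param n_items items per scale (9 for an inattention-type scale).
#' @param levels 5 or 7 response levels.
#' @param thresholds strictly increasing cut points (length `levels - 1`);
#'   default equally spaced, symmetric about 0, step 0.5 latent SD units.
#' @param item_sd SD of the per-item noise.
#' @return numeric vector of scale scores.
#' @export
simulate_likert_scores <- function(latent, n_items = 9L, levels = 5L,
                                   thresholds = NULL, item_sd = 1) {
  if (!levels %in% c(5L, 7L)) stop("levels must be 5 or 7")
  if (is.null(thresholds)) {
    k <- (levels - 2L) / 2
    thresholds <- seq(-k, k, by = 1) * 0.5
  }
  if (length(thresholds) != levels - 1L)
    stop("need ", levels - 1L, " thresholds")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be increasing")
  half <- (levels - 1L) / 2
  vapply(latent, function(lv) {
    noisy <- lv + rnorm(n_items, 0, item_sd)
    codes <- findInterval(noisy, thresholds) - half
    mean(codes)
  }, numeric(1))
}

#' Simulate realignment parameters for one subject
#'
#' Random-walk increments on the six rigid-body parameters plus occasional
#' spikes; the first frame is the zero reference. Deterministic given
#' `seed`.
#'
#' @param n_frames frames in the run (default 150).
#' @param drift_sd per-frame random-walk increment SD (mm for translations;
#'   rotations use `drift_sd / 50` rad).
#' @param spike_prob per-frame probability of a transient spike.
#' @param spike_scale spike magnitude, mm.
#' @param seed integer seed.
#' @param subject_id subject label.
#' @return a [rigid_motion_series()].
#' @export
simulate_motion_params <- function(n_frames = 150L, drift_sd = 0.02,
                                   spike_prob = 0.01, spike_scale = 1,
                                   seed = 1L, subject_id = "sim") {
  stopifnot(n_frames >= 2L)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  trans <- matrix(0, n_frames, 3L)
  rot <- matrix(0, n_frames, 3L)
  for (i in 2:n_frames) {
    trans[i, ] <- trans[i - 1L, ] + rnorm(3L, 0, drift_sd)
    rot[i, ] <- rot[i - 1L, ] + rnorm(3L, 0, drift_sd / 50)
  }
  # transient spikes: the head jerks for one frame and returns to the walk
  spikes <- which(runif(n_frames - 1L) < spike_prob) + 1L
  for (i in spikes) trans[i, ] <- trans[i, ] + rnorm(3L, 0, spike_scale)
  suppressWarnings(
    rigid_motion_series(subject_id, trans, rot, dialect = "spm"))
}
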