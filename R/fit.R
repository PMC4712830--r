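# Maximum-likelihood fitting of twin models: deterministic multi-start
# quasi-Newton minimisation of the FIML objective, likelihood-ratio tests,
# profile-likelihood confidence intervals and variance standardisation.

# Moment-based start values in template order.
moment_start <- function(prep, spec) {
  tpl <- prep$template
  start <- setNames(numeric(length(tpl$names)), tpl$names)
  mo <- prep$moments
  p <- prep$p
  tr_of <- function(name) {
    for (t in seq_len(p)) if (grepl(spec$traits[t], name, fixed = TRUE))
      return(t)
    1L
  }
  for (nm in tpl$names[seq_len(tpl$n_mean)]) {
    if (startsWith(nm, "mu.")) start[nm] <- mo$mean[tr_of(nm)]
    else start[nm] <- 0
  }
  covnames <- tpl$names[-seq_len(tpl$n_mean)]
  if (spec$type == "saturated") {
    for (nm in covnames) {
      t <- 1L
      if (startsWith(nm, "v.")) start[nm] <- mo$var[t]
      else if (startsWith(nm, "c.")) {
        # average double-entered covariance over classes in this cov class
        lbl <- sub("^c\\.", "", nm)
        vals <- unlist(lapply(seq_along(prep$classes), function(ci) {
          cl <- prep$classes[[ci]]
          if (cl$kind == "pair" && identical(cl$cov_label, lbl))
            mo$cross[ci] else NULL
        }))
        vals <- vals[is.finite(vals)]
        start[nm] <- if (length(vals)) mean(vals) else 0.2 * mo$var[t]
      }
    }
    return(start)
  }
  shares0 <- c(A = 0.4, C = 0.2, D = 0.3)
  e0 <- 1 - sum(shares0[setdiff(spec$components, "E")])
  for (nm in covnames) {
    if (startsWith(nm, "l.")) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
      X <- parts[2L]
      ij <- parts[length(parts)]
      i <- as.integer(substr(ij, 1L, 1L)); j <- as.integer(substr(ij, 2L, 2L))
      sh <- if (X == "E") e0 else shares0[[X]]
      start[nm] <- if (i == j) sqrt(sh * mo$var[i]) else 0
    } else if (startsWith(nm, "v.")) {
      start[nm] <- mo$var[tr_of(nm)]
    } else if (startsWith(nm, "sh.")) {
      X <- strsplit(nm, ".", fixed = TRUE)[[1L]][2L]
      start[nm] <- shares0[[X]]
    } else if (startsWith(nm, "r.") || nm == "rp") {
      start[nm] <- mo$r12
    } else if (nm == "rg_mf") {
      start[nm] <- 0.9
    } else if (startsWith(nm, "s.")) {
      start[nm] <- 0
    } else if (startsWith(nm, "kappa.")) {
      start[nm] <- 1
    }
  }
  start
}

perturb_start <- function(start, tpl, scale = 0.25) {
  out <- start
  for (i in seq_along(out)) {
    lo <- tpl$lower[i]; hi <- tpl$upper[i]
    step <- if (is.finite(lo) && is.finite(hi)) scale * (hi - lo) / 4
            else scale * (abs(out[i]) + 0.3)
    out[i] <- out[i] + rnorm(1L, 0, step)
    if (out[i] <= lo) out[i] <- lo + 0.05 * min(1, if (is.finite(hi)) hi - lo else 1)
    if (out[i] >= hi) out[i] <- hi - 0.05 * min(1, if (is.finite(lo)) hi - lo else 1)
  }
  out
}

num_gradient <- function(fn, x, h = 1e-6, lower = -Inf, upper = Inf) {
  g <- numeric(length(x))
  lower <- rep_len(lower, length(x))
  upper <- rep_len(upper, length(x))
  f0 <- NULL
  for (i in seq_along(x)) {
    hi <- h * (1 + abs(x[i]))
    up <- x[i] + hi <= upper[i]
    dn <- x[i] - hi >= lower[i]
    xp <- x; xm <- x
    if (up && dn) {
      xp[i] <- x[i] + hi; xm[i] <- x[i] - hi
      g[i] <- (fn(xp) - fn(xm)) / (2 * hi)
    } else {
      if (is.null(f0)) f0 <- fn(x)
      if (up) {
        xp[i] <- x[i] + hi
        g[i] <- (fn(xp) - f0) / hi
      } else {
        xm[i] <- x[i] - hi
        g[i] <- (f0 - fn(xm)) / hi
      }
    }
  }
  g
}

#' Fit a twin model by full-information maximum likelihood
#'
#' Minimises [fiml_neg2ll()] with a bounded quasi-Newton optimiser
#' (`nlminb`) from a moment-based start plus seeded random perturbations
#' (deterministic multi-start). The best converged solution is returned;
#' when no start converges the best non-converged solution is returned with
#' `converged = FALSE`, never dropped silently.
#'
#' @param dataset a [twin_dataset()].
#' @param spec a [twin_model()] or [saturated_model()].
#' @param starts optional list of full named start vectors (overrides the
#'   generated starts).
#' @param seed integer seed for the start perturbations.
#' @param n_starts number of starts (>= 1; default 5).
#' @param fix named numeric vector of parameters held fixed (e.g.
#'   `c(r.A = 0)` for the no-genetic-correlation null).
#' @param control passed to [stats::nlminb()] (defaults: `rel.tol 1e-8`,
#'   `iter.max 500`).
#' @return An object of class `twin_fit` with elements `spec`, `estimates`
#'   (full named vector), `minus2lnL`, `n_params` (free parameters),
#'   `converged`, `gradient_norm`, and `standardized` (see
#'   [standardize()]).
#' @export
fit_model <- function(dataset, spec, starts = NULL, seed = 1L, n_starts = 5L,
                      fix = NULL, control = list()) {
  prep <- prepare_fiml(dataset, spec)
  fit_model_prepared(prep, spec, starts = starts, seed = seed,
                     n_starts = n_starts, fix = fix, control = control)
}

# Core fitter on a prepared dataset (reused by profile_ci for warm starts).
# Mean parameters are generalized-least-squares-profiled out of the
# likelihood inside the C++ kernel, so the optimizer only sees the
# covariance parameters.
fit_model_prepared <- function(prep, spec, starts = NULL, seed = 1L,
                               n_starts = 5L, fix = NULL, control = list()) {
  tpl <- prep$template
  nm <- tpl$names
  nmean <- tpl$n_mean
  mean_names <- nm[seq_len(nmean)]
  cov_names <- nm[-seq_len(nmean)]
  if (!is.null(fix) && !all(names(fix) %in% nm))
    stop("unknown fixed parameters: ",
         paste(setdiff(names(fix), nm), collapse = ", "))
  fix_mean <- fix[names(fix) %in% mean_names]
  fix_cov <- fix[names(fix) %in% cov_names]
  mean_fixed_cols <- match(names(fix_mean), mean_names)
  mean_free_cols <- setdiff(seq_len(nmean), mean_fixed_cols)
  cov_free <- setdiff(cov_names, names(fix_cov))
  cov_free_idx <- match(cov_free, nm)
  classes <- prep$classes
  patterns <- prep$patterns

  use_mom <- !isTRUE(spec$contrast)   # contrast mixes means per evaluation
  plan <- compile_sigma_plan(spec, classes, cov_names)
  cov_free_pos <- match(cov_free, cov_names)
  cov_fix_pos <- match(names(fix_cov), cov_names)
  pc_base <- numeric(length(cov_names))
  if (length(cov_fix_pos)) pc_base[cov_fix_pos] <- as.numeric(fix_cov)
  eval_profiled <- function(par_cov_free) {
    pc <- pc_base
    pc[cov_free_pos] <- par_cov_free
    sg <- sigma_from_plan(plan, pc)
    if (is.null(sg)) return(list(value = BIG_PENALTY, theta = NULL))
    res <- if (use_mom)
      fiml_profiled_mom(sg$S, patterns, as.integer(mean_free_cols),
                        as.integer(mean_fixed_cols), as.numeric(fix_mean))
    else
      fiml_profiled(sg$S, sg$G, patterns, as.integer(mean_free_cols),
                    as.integer(mean_fixed_cols), as.numeric(fix_mean))
    if (!is.finite(res$value)) res$value <- BIG_PENALTY
    res
  }
  obj_free <- function(par_cov_free) eval_profiled(par_cov_free)$value

  if (is.null(starts)) {
    s0 <- moment_start(prep, spec)
    starts <- list(s0)
    if (n_starts > 1L) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      for (k in seq_len(n_starts - 1L))
        starts[[k + 1L]] <- perturb_start(s0, tpl, scale = 0.15 + 0.1 * k)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
  }
  lower <- tpl$lower[cov_free_idx]
  upper <- tpl$upper[cov_free_idx]
  ctrl <- modifyList(list(rel.tol = 1e-8, iter.max = 300L, eval.max = 1500L),
                     control)
  # two-phase multistart: short exploratory runs from every start, then a
  # full-tolerance polish of the incumbent
  ctrl_quick <- modifyList(ctrl, list(iter.max = 40L, eval.max = 400L))
  best <- NULL
  for (ks in seq_along(starts)) {
    s <- starts[[ks]]
    sf <- pmin(pmax(as.numeric(s[cov_free]), lower), upper)
    res <- tryCatch(
      nlminb(sf, obj_free, lower = lower, upper = upper,
             control = if (length(starts) > 1L) ctrl_quick else ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- res$convergence == 0 && res$objective < BIG_PENALTY
    if (is.null(best) ||
        (conv && !best$conv) ||
        (res$objective < best$objective - 1e-9)) {
      best <- list(par = res$par, objective = res$objective, conv = conv,
                   message = res$message)
    }
  }
  if (!is.null(best) && length(starts) > 1L) {
    res <- tryCatch(
      nlminb(best$par, obj_free, lower = lower, upper = upper,
             control = ctrl),
      error = function(e) NULL)
    if (!is.null(res) && res$objective <= best$objective + 1e-9) {
      # a polish that cannot improve an already-converged incumbent may
      # report "false convergence"; the incumbent's status then stands
      conv <- (res$convergence == 0 || best$conv) &&
        res$objective < BIG_PENALTY
      best <- list(par = res$par, objective = res$objective, conv = conv,
                   message = res$message)
    }
  }
  n_free <- length(cov_free) + length(mean_free_cols)
  if (is.null(best))
    return(structure(list(spec = spec, estimates = NULL, minus2lnL = NA_real_,
                          n_params = n_free, converged = FALSE,
                          message = "all starts failed",
                          gradient_norm = NA_real_, standardized = NULL),
                     class = "twin_fit"))
  final <- eval_profiled(best$par)
  full <- setNames(numeric(length(nm)), nm)
  full[mean_free_cols] <- final$theta
  if (length(mean_fixed_cols)) full[mean_fixed_cols] <- as.numeric(fix_mean)
  full[cov_free] <- best$par
  if (length(fix_cov)) full[names(fix_cov)] <- as.numeric(fix_cov)
  gn <- sqrt(sum(num_gradient(obj_free, best$par, lower = lower,
                              upper = upper)^2))
  # optimizer return code 0, or the gradient-norm check at the solution
  converged <- best$conv ||
    (is.finite(gn) && gn <= 1e-5 * (1 + abs(best$objective)))
  fit <- structure(
    list(spec = spec, estimates = full, minus2lnL = best$objective,
         n_params = n_free, converged = converged,
         message = best$message, gradient_norm = gn,
         free_names = c(mean_names[mean_free_cols], cov_free), fixed = fix,
         n_families = prep$n_families),
    class = "twin_fit")
  fit$standardized <- tryCatch(standardize(fit), error = function(e) NULL)
  fit
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("<twin_fit> -2lnL = %.4f, %d free parameters, converged: %s\n",
              x$minus2lnL, x$n_params, x$converged))
  if (!is.null(x$standardized) && !is.null(x$standardized$shares)) {
    cat("  standardized shares:\n")
    print(round(x$standardized$shares, 3))
    st <- x$standardized
    if (!is.null(st$rp))
      cat(sprintf("  rp = %.3f", st$rp),
          if (!is.null(st$rg)) sprintf(" rg = %.3f", st$rg),
          if (!is.null(st$re)) sprintf(" re = %.3f", st$re), "\n")
  }
  invisible(x)
}

#' Standardised variance shares and cross-trait correlations
#'
#' Per-trait proportions of variance from each component (heritability for
#' A), and for two-trait models the component correlations: genetic
#' `rg = SigmaA[1,2]/sqrt(SigmaA[1,1] SigmaA[2,2])`, environmental `re`
#' likewise from SigmaE, and phenotypic `rp` from the summed latent
#' covariance. For AE models `rp = rg*sqrt(h2_1 h2_2) + re*sqrt(e2_1 e2_2)`
#' holds exactly. Under a general sex-limitation model shares are reported
#' per sex.
#'
#' @param fit a converged `twin_fit` for a biometric spec.
#' @return list with `shares` (components x traits matrix, or per-sex list)
#'   and, for 2 traits, `rg`, `re`, `rp` (plus per-component correlations).
#' @export
standardize <- function(fit) {
  spec <- fit$spec
  if (spec$type != "biometric") return(NULL)
  par <- as.list(fit$estimates)
  cs <- component_sigmas(spec, par)
  if (is.null(cs)) stop("estimates outside the model space")
  p <- length(spec$traits)
  one_sex <- function(set) {
    tot <- Reduce(`+`, lapply(set, `[[`, "S"))
    shares <- sapply(set, function(x) diag(x$S) / diag(tot))
    shares <- matrix(shares, nrow = p,
                     dimnames = list(spec$traits, names(set)))
    out <- list(shares = t(shares), total = tot)
    if (p == 2L) {
      ccor <- function(S) {
        den <- sqrt(S[1L, 1L] * S[2L, 2L])
        if (den < 1e-12) NA_real_ else S[1L, 2L] / den
      }
      out$component_cor <- vapply(set, function(x) ccor(x$S), numeric(1))
      out$rg <- unname(out$component_cor["A"])
      out$re <- unname(out$component_cor["E"])
      out$rp <- ccor(tot)
    }
    out
  }
  if (spec$sex_limitation == "general") {
    resF <- one_sex(cs$F); resM <- one_sex(cs$M)
    return(list(by_sex = list(F = resF, M = resM),
                shares = list(F = resF$shares, M = resM$shares)))
  }
  one_sex(cs$F)
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,nested `twin_fit` objects; `nested` must be a constrained
#'   version of `full`.
#' @param refit optional list `(dataset)` enabling an automatic refit of the
#'   nested model from the full model's estimates when the statistic is
#'   negative beyond tolerance.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt <- function(full, nested, refit = NULL) {
  if (!isTRUE(full$converged) || !isTRUE(nested$converged))
    warning("LRT on non-converged fit(s)")
  stat <- nested$minus2lnL - full$minus2lnL
  df <- full$n_params - nested$n_params
  if (df < 0L) stop("'nested' has more free parameters than 'full'")
  if (stat < -1e-6 && !is.null(refit)) {
    st <- nested$estimates
    common <- intersect(names(st), names(full$estimates))
    st[common] <- full$estimates[common]
    re <- fit_model(refit$dataset, nested$spec, starts = list(st),
                    fix = nested$fixed)
    if (re$minus2lnL < nested$minus2lnL) nested <- re
    stat <- nested$minus2lnL - full$minus2lnL
  }
  if (stat < -1e-6)
    stop("negative LRT statistic (", format(stat),
         "): the 'full' fit did not reach its optimum")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Profile-likelihood confidence interval
#'
#' Endpoints are the values of the named parameter at which the profiled
#' -2 log-likelihood exceeds its minimum by the chi-square(1) quantile
#' (3.841 at 95%), located by bisection. When the profile stays below the
#' threshold all the way to a box bound (e.g. a correlation reaching 1), the
#' bound is returned as the endpoint and flagged.
#'
#' @param dataset a [twin_dataset()].
#' @param spec the model specification of `fit`.
#' @param fit a converged `twin_fit`.
#' @param param name of a free parameter of `fit` (use the `"share"`
#'   parameterization to profile heritabilities and component correlations
#'   directly).
#' @param level confidence level (default 0.95).
#' @param tol bisection tolerance on the parameter scale.
#' @return numeric `c(lower, upper)` with attributes `at_bound` (logical
#'   pair) and `level`.
#' @export
profile_ci <- function(dataset, spec, fit, param, level = 0.95, tol = 1e-4) {
  if (!param %in% fit$free_names) stop(param, " is not a free parameter")
  prep <- prepare_fiml(dataset, spec)
  tpl <- prep$template
  i <- match(param, tpl$names)
  mle <- fit$estimates[[param]]
  target <- fit$minus2lnL + qchisq(level, 1L)
  warm <- fit$estimates
  pfun <- function(val) {
    fx <- c(setNames(val, param), fit$fixed)
    f <- fit_model_prepared(prep, spec, starts = list(warm), fix = fx,
                            n_starts = 1L)
    if (isTRUE(f$converged) || f$minus2lnL < BIG_PENALTY)
      warm <<- f$estimates
    f$minus2lnL
  }
  one_side <- function(dir) {
    bound <- if (dir < 0) tpl$lower[i] else tpl$upper[i]
    step <- if (is.finite(bound)) abs(bound - mle) / 4
            else max(0.25 * (abs(mle) + 0.5), 0.1)
    x_in <- mle
    x_out <- NA_real_
    x <- mle
    repeat {
      x <- if (is.finite(bound)) min(max(x + dir * step, tpl$lower[i]),
                                     tpl$upper[i])
           else x + dir * step
      v <- pfun(x)
      if (v >= target) { x_out <- x; break }
      x_in <- x
      if (is.finite(bound) && abs(x - bound) < tol)
        return(list(end = bound, at_bound = TRUE))
      step <- step * 1.6
    }
    while (abs(x_out - x_in) > tol) {
      mid <- (x_out + x_in) / 2
      if (pfun(mid) >= target) x_out <- mid else x_in <- mid
    }
    list(end = (x_out + x_in) / 2, at_bound = FALSE)
  }
  lo <- one_side(-1)
  warm <- fit$estimates
  hi <- one_side(+1)
  out <- c(lo$end, hi$end)
  attr(out, "at_bound") <- c(lo$at_bound, hi$at_bound)
  attr(out, "level") <- level
  out
}
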