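# Full-information ML objective: families are grouped into patterns sharing
# a covariance class (zygosity group x sex composition x family size) and an
# observed-slot mask; the C++ kernel then does one Cholesky per pattern.

# Assemble classes and patterns for a dataset under a given spec.
prepare_fiml <- function(dataset, spec) {
  p <- length(spec$traits)
  miss_tr <- setdiff(spec$traits, dataset$traits)
  if (length(miss_tr))
    stop("dataset lacks traits: ", paste(miss_tr, collapse = ", "))
  fams <- split_families(dataset)

  class_key <- character(0)
  classes <- list()
  get_class <- function(kind, group, sexes) {
    key <- paste(kind, group, paste(sexes, collapse = ""), sep = "|")
    i <- match(key, class_key)
    if (!is.na(i)) return(i)
    cl <- list(kind = kind, group = group, sexes = sexes,
               mean_label = group)
    if (spec$type == "saturated") {
      vmap <- spec$sat$var_classes; cmap <- spec$sat$cov_classes
      if (!group %in% names(vmap))
        stop("saturated var_classes has no entry for group ", group)
      cl$var_label <- vmap[[group]]
      cl$cov_label <- if (kind == "pair") {
        if (!group %in% names(cmap))
          stop("saturated cov_classes has no entry for group ", group)
        cmap[[group]]
      } else NA
    }
    class_key[length(classes) + 1L] <<- key
    classes[[length(classes) + 1L]] <<- cl
    length(classes)
  }

  covs <- spec$covariates
  fam_rows <- list()
  n_dropped <- 0L
  for (fam in fams) {
    m <- nrow(fam)
    y <- as.numeric(t(as.matrix(fam[, spec$traits, drop = FALSE])))
    obs <- which(!is.na(y))
    if (!length(obs)) next
    # covariate matrix: members x covariates
    xc <- matrix(0, m, length(covs),
                 dimnames = list(NULL, covs))
    bad <- FALSE
    for (j in seq_along(covs)) {
      vals <- fam[[covs[j]]]
      if (is.null(vals)) stop("dataset lacks covariate column ", covs[j])
      obs_member <- unique(ceiling(obs / p))
      if (any(is.na(vals[obs_member]))) bad <- TRUE
      vals[is.na(vals)] <- 0
      xc[, j] <- as.numeric(vals)
    }
    if (bad) { n_dropped <- n_dropped + 1L; next }
    sexes <- fam$sex
    if (m == 2L) {
      grp <- effective_group(fam$zygosity[1L], sexes)
      cls <- get_class("pair", grp, sexes)
    } else {
      grp <- effective_group_single(fam$zygosity[1L], sexes[1L])
      cls <- get_class("single", grp, sexes[1L])
    }
    fam_rows[[length(fam_rows) + 1L]] <-
      list(cls = cls, obs = obs, y = y[obs], x = xc, m = m,
           birth = fam$birth_order)
  }
  if (n_dropped > 0L)
    warning(n_dropped, " families dropped: missing covariate values for ",
            "members with observed phenotypes")
  if (!length(fam_rows)) stop("no usable families")

  tpl <- par_template(spec, classes)
  terms <- tpl$terms

  # group families into patterns
  keys <- vapply(fam_rows, function(fr)
    paste(fr$cls, paste(fr$obs, collapse = ","), sep = "|"), character(1))
  patterns <- lapply(split(seq_along(fam_rows), keys), function(ix) {
    frs <- fam_rows[ix]
    fr1 <- frs[[1L]]
    n <- length(frs)
    nslot <- fr1$m * p
    Y <- do.call(rbind, lapply(frs, `[[`, "y"))
    q <- length(terms)
    D <- matrix(0, n * nslot, q)
    cl <- classes[[fr1$cls]]
    for (qi in seq_len(q)) {
      tm <- terms[[qi]]
      if (!is.na(tm$class_label) && tm$class_label != cl$mean_label) next
      for (mem in seq_len(fr1$m)) {
        if (!is.na(tm$member) && tm$member != mem) next
        slot <- (mem - 1L) * p + tm$trait
        rows <- (slot - 1L) * n + seq_len(n)
        if (is.na(tm$covariate)) {
          D[rows, qi] <- 1
        } else {
          D[rows, qi] <- vapply(frs, function(fr) fr$x[mem, tm$covariate],
                                numeric(1))
        }
      }
    }
    # per-slot designs and cross-moments for the profiled fast path
    k <- length(fr1$obs)
    Da <- lapply(seq_len(k), function(a)
      D[(fr1$obs[a] - 1L) * n + seq_len(n), , drop = FALSE])
    Syy <- crossprod(Y)
    U <- matrix(0, k * k, q)
    Tm <- matrix(0, k * k * q, q)
    for (a in seq_len(k)) {
      UA <- crossprod(Da[[a]], Y)       # q x k
      for (bb in seq_len(k)) {
        blk <- (a - 1L) * k + bb
        U[blk, ] <- UA[, bb]
        Tm[(blk - 1L) * q + seq_len(q), ] <- crossprod(Da[[a]], Da[[bb]])
      }
    }
    list(cls = fr1$cls, idx = as.integer(fr1$obs), Y = Y, D = D,
         nslot = as.integer(nslot), n = as.integer(n),
         Syy = Syy, U = U, T = Tm)
  })
  names(patterns) <- NULL

  # per-class, per-trait sample moments for start values
  moments <- summarize_class_moments(fam_rows, classes, p)

  list(classes = classes, patterns = patterns, template = tpl,
       n_families = length(fam_rows), moments = moments, p = p)
}

effective_group_single <- function(zygosity, sex) {
  if (zygosity != "SIB") return(zygosity)
  if (sex == "F") "DZF" else "DZM"
}

summarize_class_moments <- function(fam_rows, classes, p) {
  all_y <- matrix(NA_real_, 0L, p)
  for (fr in fam_rows) {
    ym <- matrix(NA_real_, fr$m, p)
    ym[fr$obs] <- fr$y  # obs indexes t(member x trait) flattened member-major
    # fr$y holds y[obs] where y was member-major flattened: slot (m-1)p+t
    all_y <- rbind(all_y, matrix(NA_real_, fr$m, p))
    for (k in seq_along(fr$obs)) {
      slot <- fr$obs[k]
      mem <- ceiling(slot / p); tr <- slot - (mem - 1L) * p
      all_y[nrow(all_y) - fr$m + mem, tr] <- fr$y[k]
    }
  }
  mu <- colMeans(all_y, na.rm = TRUE)
  v <- apply(all_y, 2L, var, na.rm = TRUE)
  # double-entered cross-member covariance per class (first trait only)
  cross <- lapply(seq_along(classes), function(ci) {
    ys <- lapply(fam_rows, function(fr) {
      if (fr$cls != ci || fr$m != 2L) return(NULL)
      y1 <- fr$obs == 1L; y2 <- fr$obs == (p + 1L)
      if (any(y1) && any(y2)) c(fr$y[which(y1)], fr$y[which(y2)]) else NULL
    })
    ys <- do.call(rbind, ys[!vapply(ys, is.null, logical(1))])
    if (is.null(ys) || nrow(ys) < 3L) return(NA_real_)
    de <- rbind(ys, ys[, 2:1])
    cov(de[, 1L], de[, 2L])
  })
  r <- suppressWarnings(if (p >= 2L)
    cor(all_y[, 1L], all_y[, 2L], use = "complete.obs") else NA_real_)
  if (!is.finite(r)) r <- 0
  list(mean = mu, var = v, cross = unlist(cross), r12 = r)
}

#' FIML -2 log-likelihood of a model on a twin dataset
#'
#' Sum over families of minus twice the multivariate-normal log density of
#' each family's observed phenotypes under the model-implied moments,
#' marginalised to the observed subset (singletons contribute their marginal
#' density). Returns `Inf` when the implied covariance is not positive
#' definite on some observed subset.
#'
#' @param dataset a [twin_dataset()].
#' @param spec a [twin_model()] or [saturated_model()].
#' @param params full named parameter vector (see
#'   [fit_model()]`$estimates` for the naming scheme).
#' @return scalar -2 log-likelihood.
#' @export
fiml_neg2ll <- function(dataset, spec, params) {
  prep <- prepare_fiml(dataset, spec)
  nm <- prep$template$names
  if (!all(nm %in% names(params)))
    stop("params lacks entries: ",
         paste(setdiff(nm, names(params)), collapse = ", "))
  obj <- make_objective(prep, spec)
  val <- obj(as.numeric(params[nm]))
  if (val >= BIG_PENALTY) Inf else val
}

BIG_PENALTY <- 1e10

# Closure evaluating the objective for a full parameter vector in template
# order; out-of-model values map to a large finite penalty so optimizers can
# recover.
make_objective <- function(prep, spec) {
  nmean <- prep$template$n_mean
  nm <- prep$template$names
  classes <- prep$classes
  patterns <- prep$patterns
  function(par_full) {
    names(par_full) <- nm
    sg <- build_sigma_list(spec, as.list(par_full), classes)
    if (is.null(sg)) return(BIG_PENALTY)
    val <- fiml_core(par_full[seq_len(nmean)], sg$S, sg$G, patterns)
    if (!is.finite(val)) BIG_PENALTY else val
  }
}
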