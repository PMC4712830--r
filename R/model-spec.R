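# Variance-component model family: saturated and biometric (ACE/ADE/AE/...)
# specifications, their parameter templates, and the implied-moment builders
# evaluated inside the FIML objective.
#
# Slot layout for a pair: slots 1..p are member 1's traits, p+1..2p member
# 2's, members ordered by birth order.

#' Cross-member correlation of a variance component
#'
#' Biometrical expectations for the correlation of a component's scores
#' across the two members of a pair: additive genetic (A) 1 in MZ pairs and
#' 0.5 in DZ/sibling pairs, dominance (D) 1 and 0.25, shared environment (C)
#' 1 everywhere, unique environment (E) 0. For opposite-sex DZ pairs the A
#' correlation is additionally scaled by the cross-sex genetic correlation
#' `rg_mf`.
#'
#' @param component one of `"A", "C", "D", "E"`.
#' @param zygosity_group one of `MZF, MZM, DZF, DZM, DZOS, SIB`.
#' @param rg_mf cross-sex genetic correlation (default 1).
#' @return scalar correlation.
#' @export
component_correlation <- function(component, zygosity_group, rg_mf = 1) {
  component <- match.arg(component, c("A", "C", "D", "E"))
  zygosity_group <- match.arg(zygosity_group, ZYGOSITY_GROUPS)
  mz <- zygosity_group %in% c("MZF", "MZM")
  switch(component,
    A = if (mz) 1 else if (zygosity_group == "DZOS") 0.5 * rg_mf else 0.5,
    D = if (mz) 1 else 0.25,
    C = 1,
    E = 0)
}

#' Define a biometric variance-component model
#'
#' @param traits character vector (1-3 trait column names).
#' @param components subset of `c("A","C","D","E")`; `"E"` is mandatory and
#'   `"C"`/`"D"` are mutually exclusive.
#' @param covariates character vector of covariate column names entering the
#'   mean model with one coefficient per trait (e.g. `"sex_male"`,
#'   `"age_scan"`).
#' @param parameterization `"cholesky"` (lower-triangular paths per
#'   component, any number of traits), `"share"` (total variance plus
#'   variance shares and component correlations, 1-2 traits; used for direct
#'   profiling of heritabilities and genetic correlations) or `"share_rp"`
#'   (as `"share"` for two AE traits but with the phenotypic correlation as
#'   the free parameter and the E correlation derived, used to test rp = 0).
#' @param sex_limitation `"none"` or `"general"` (sex-specific path sets plus
#'   a cross-sex genetic correlation for opposite-sex pairs).
#' @param rg_mf_free when `sex_limitation = "general"`, estimate the
#'   cross-sex genetic correlation instead of fixing it.
#' @param rg_mf fixed value of the cross-sex genetic correlation.
#' @param contrast include a reciprocal sibling-contrast path `s` per trait
#'   (`Sigma* = (I-B)^{-1} Sigma (I-B)^{-T}` with `B` placing `s` on the
#'   cross-member same-trait positions; means are transformed likewise).
#' @param scale_groups zygosity groups whose total covariance gets a free
#'   multiplicative scale (e.g. `"DZOS"` to let opposite-sex pair variance
#'   differ).
#' @return An object of class `twin_model_spec`.
#' @export
twin_model <- function(traits, components = c("A", "E"),
                       covariates = character(0),
                       parameterization = c("cholesky", "share", "share_rp"),
                       sex_limitation = c("none", "general"),
                       rg_mf_free = FALSE, rg_mf = 1,
                       contrast = FALSE, scale_groups = character(0)) {
  parameterization <- match.arg(parameterization)
  sex_limitation <- match.arg(sex_limitation)
  components <- unique(match.arg(components, c("A", "C", "D", "E"),
                                 several.ok = TRUE))
  if (!"E" %in% components) stop("the E component is mandatory")
  if (all(c("C", "D") %in% components))
    stop("C and D are not jointly identified in twin-pair data")
  p <- length(traits)
  if (p < 1L || p > 3L) stop("1 to 3 traits supported")
  if (parameterization %in% c("share", "share_rp") && p > 2L)
    stop("the share parameterization supports at most 2 traits")
  if (parameterization == "share_rp" &&
      !(p == 2L && setequal(components, c("A", "E"))))
    stop("share_rp requires a bivariate AE model")
  if (parameterization != "cholesky" && sex_limitation != "none")
    stop("sex limitation requires the cholesky parameterization")
  if (contrast && parameterization != "cholesky")
    stop("the contrast model requires the cholesky parameterization")
  structure(
    list(type = "biometric", traits = traits, components = components,
         covariates = covariates, parameterization = parameterization,
         sex_limitation = sex_limitation, rg_mf_free = rg_mf_free,
         rg_mf = rg_mf, contrast = contrast,
         scale_groups = scale_groups),
    class = "twin_model_spec")
}

#' Define a saturated (unstructured) model
#'
#' Free means, variances and cross-member covariances for a single trait,
#' with equality structure expressed by mapping zygosity groups to shared
#' classes. Sibling pairs are folded into the DZ group matching their sex
#' composition before the maps apply. The reference model for the
#' likelihood-ratio homogeneity battery.
#'
#' @param trait one trait column name.
#' @param covariates covariate column names for the mean model.
#' @param var_classes,cov_classes named character vectors mapping group
#'   labels (`MZF, MZM, DZF, DZM, DZOS`) to class labels; groups sharing a
#'   class share the parameter. The special cov class `"zero"` fixes the
#'   cross-member covariance to 0. Defaults give every group its own
#'   parameter.
#' @param group_means free mean per group class (otherwise one common mean).
#' @param birth_order_mean add a free mean offset for second-born members.
#' @param symmetric if `FALSE`, members of a pair get separate means and
#'   variances (the fully saturated 2x2 case used to check the
#'   sample-moments identity).
#' @return An object of class `twin_model_spec`.
#' @export
saturated_model <- function(trait, covariates = character(0),
                            var_classes = NULL, cov_classes = NULL,
                            group_means = FALSE, birth_order_mean = FALSE,
                            symmetric = TRUE) {
  groups <- c("MZF", "MZM", "DZF", "DZM", "DZOS")
  if (is.null(var_classes)) var_classes <- setNames(groups, groups)
  if (is.null(cov_classes)) cov_classes <- setNames(groups, groups)
  structure(
    list(type = "saturated", traits = trait, covariates = covariates,
         sat = list(var_classes = var_classes, cov_classes = cov_classes,
                    group_means = group_means,
                    birth_order_mean = birth_order_mean,
                    symmetric = symmetric)),
    class = "twin_model_spec")
}

#' @export
print.twin_model_spec <- function(x, ...) {
  if (x$type == "biometric") {
    cat(sprintf("<twin_model_spec> %s model for %s (%s)\n",
                paste(x$components, collapse = ""),
                paste(x$traits, collapse = " x "), x$parameterization))
    if (x$sex_limitation != "none") cat("  general sex limitation\n")
    if (isTRUE(x$contrast)) cat("  sibling contrast path\n")
  } else {
    cat(sprintf("<twin_model_spec> saturated model for %s\n", x$traits))
  }
  if (length(x$covariates))
    cat("  mean covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# Effective group label: SIB pairs take the DZ label matching their sexes.
effective_group <- function(zygosity, sexes) {
  if (zygosity != "SIB") return(zygosity)
  if (length(sexes) == 2L && sexes[1L] != sexes[2L]) return("DZOS")
  if (sexes[1L] == "F") "DZF" else "DZM"
}

# ---- mean terms ------------------------------------------------------------

# Each mean term defines one column of the design matrix: an intercept or a
# covariate slope, possibly restricted to a member index or a group class.
mean_terms <- function(spec, classes) {
  traits <- spec$traits
  p <- length(traits)
  terms <- list()
  add <- function(name, trait, member = NA, class_label = NA, covariate = NA)
    terms[[length(terms) + 1L]] <<- list(name = name, trait = trait,
                                         member = member,
                                         class_label = class_label,
                                         covariate = covariate)
  sat <- spec$type == "saturated"
  if (sat && isTRUE(spec$sat$group_means)) {
    labels <- unique(vapply(classes, function(cl) cl$mean_label, character(1)))
    for (t in seq_len(p)) for (lb in labels) {
      if (isTRUE(spec$sat$symmetric)) {
        add(paste0("mu.", traits[t], ".", lb), t, class_label = lb)
      } else {
        add(paste0("mu.", traits[t], ".", lb, ".m1"), t, member = 1L,
            class_label = lb)
        add(paste0("mu.", traits[t], ".", lb, ".m2"), t, member = 2L,
            class_label = lb)
      }
    }
  } else {
    for (t in seq_len(p)) add(paste0("mu.", traits[t]), t)
  }
  if (sat && isTRUE(spec$sat$birth_order_mean))
    for (t in seq_len(p)) add(paste0("bo.", traits[t]), t, member = 2L)
  for (t in seq_len(p)) for (cv in spec$covariates)
    add(paste0("b.", traits[t], ".", cv), t, covariate = cv)
  terms
}

# ---- parameter templates ---------------------------------------------------

chol_names <- function(prefix, p) {
  out <- character(0)
  for (j in seq_len(p)) for (i in j:p)
    out <- c(out, paste0(prefix, ".", i, j))
  out
}

# Returns list(names, lower, upper) for the covariance part of the model.
cov_par_template <- function(spec, classes) {
  p <- length(spec$traits)
  nm <- character(0); lo <- numeric(0); hi <- numeric(0)
  add <- function(n, l, h) {
    nm <<- c(nm, n); lo <<- c(lo, rep(l, length(n))); hi <<- c(hi, rep(h, length(n)))
  }
  if (spec$type == "saturated") {
    var_lbls <- unique(vapply(classes, function(cl) cl$var_label, character(1)))
    for (lb in var_lbls) {
      if (isTRUE(spec$sat$symmetric)) add(paste0("v.", lb), 1e-8, Inf)
      else add(paste0("v.", lb, c(".m1", ".m2")), 1e-8, Inf)
    }
    cov_lbls <- unlist(lapply(classes, function(cl)
      if (cl$kind == "pair" && !identical(cl$cov_label, "zero")) cl$cov_label))
    for (lb in unique(cov_lbls)) add(paste0("c.", lb), -Inf, Inf)
    return(list(names = nm, lower = lo, upper = hi))
  }
  par9n <- spec$parameterization
  if (par9n == "cholesky") {
    sexes <- if (spec$sex_limitation == "general") c("F", "M") else ""
    for (X in spec$components) for (sx in sexes) {
      pre <- if (nzchar(sx)) paste0("l.", X, ".", sx) else paste0("l.", X)
      add(chol_names(pre, p), -Inf, Inf)
    }
    if (spec$sex_limitation == "general" && isTRUE(spec$rg_mf_free))
      add("rg_mf", -1, 1)
    if (isTRUE(spec$contrast)) add(paste0("s.", spec$traits), -0.99, 0.99)
  } else {
    for (t in spec$traits) add(paste0("v.", t), 1e-8, Inf)
    for (X in setdiff(spec$components, "E"))
      for (t in spec$traits) add(paste0("sh.", X, ".", t), 0, 1)
    if (p == 2L) {
      for (X in spec$components) {
        if (X == "E" && par9n == "share_rp") add("rp", -1, 1)
        else add(paste0("r.", X), -1, 1)
      }
    }
  }
  for (g in spec$scale_groups) add(paste0("kappa.", g), 1e-6, Inf)
  list(names = nm, lower = lo, upper = hi)
}

par_template <- function(spec, classes) {
  mt <- mean_terms(spec, classes)
  cv <- cov_par_template(spec, classes)
  mean_names <- vapply(mt, `[[`, character(1), "name")
  list(terms = mt,
       names = c(mean_names, cv$names),
       lower = c(rep(-Inf, length(mean_names)), cv$lower),
       upper = c(rep(Inf, length(mean_names)), cv$upper),
       n_mean = length(mean_names))
}

# ---- component covariance matrices ----------------------------------------

lower_tri_from <- function(par, prefix, p) {
  L <- matrix(0, p, p)
  for (j in seq_len(p)) for (i in j:p)
    L[i, j] <- par[[paste0(prefix, ".", i, j)]]
  L
}

# Component covariance matrices (and factors) at a parameter vector.
# Returns list(F = list(A = , ...), M = list(...)) of p x p matrices; without
# sex limitation both entries are the same set.  NULL signals an invalid
# (out-of-model) parameter value for the share parameterizations.
component_sigmas <- function(spec, par) {
  p <- length(spec$traits)
  if (spec$parameterization == "cholesky") {
    build <- function(sx) {
      out <- list()
      for (X in spec$components) {
        pre <- if (spec$sex_limitation == "general")
          paste0("l.", X, ".", sx) else paste0("l.", X)
        L <- lower_tri_from(par, pre, p)
        out[[X]] <- list(L = L, S = tcrossprod(L))
      }
      out
    }
    if (spec$sex_limitation == "general")
      return(list(F = build("F"), M = build("M")))
    one <- build("")
    return(list(F = one, M = one))
  }
  # share / share_rp
  v <- vapply(spec$traits, function(t) par[[paste0("v.", t)]], numeric(1))
  shares <- list()
  for (X in setdiff(spec$components, "E"))
    shares[[X]] <- vapply(spec$traits, function(t)
      par[[paste0("sh.", X, ".", t)]], numeric(1))
  if (any(unlist(shares) < 0)) return(NULL)
  e_share <- 1 - Reduce(`+`, shares, rep(0, p))
  if (any(e_share < 0)) return(NULL)
  shares$E <- e_share
  rs <- list()
  if (p == 2L) {
    for (X in spec$components) {
      if (X == "E" && spec$parameterization == "share_rp") {
        rp <- par[["rp"]]; rA <- par[["r.A"]]
        hA <- shares$A; hE <- shares$E
        den <- sqrt(hE[1L] * hE[2L])
        if (den < 1e-12) return(NULL)
        re <- (rp - rA * sqrt(hA[1L] * hA[2L])) / den
        if (abs(re) > 1) return(NULL)
        rs$E <- re
      } else rs[[X]] <- par[[paste0("r.", X)]]
    }
  }
  out <- list()
  for (X in spec$components) {
    d <- shares[[X]] * v
    S <- diag(d, p)
    if (p == 2L) S[1L, 2L] <- S[2L, 1L] <- rs[[X]] * sqrt(d[1L] * d[2L])
    # factor for cross-sex blocks unused here (no sex limitation in shares)
    out[[X]] <- list(S = S, L = NULL)
  }
  list(F = out, M = out)
}

# ---- implied moments per class --------------------------------------------

# classes: list of descriptors with fields kind ("pair"/"single"), group
# (effective label), sexes (length 2 or 1), plus saturated class labels.
build_sigma_list <- function(spec, par, classes) {
  p <- length(spec$traits)
  if (spec$type == "saturated") {
    S_list <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cl <- classes[[i]]
      if (isTRUE(spec$sat$symmetric)) {
        v1 <- v2 <- par[[paste0("v.", cl$var_label)]]
      } else {
        v1 <- par[[paste0("v.", cl$var_label, ".m1")]]
        v2 <- par[[paste0("v.", cl$var_label, ".m2")]]
      }
      if (cl$kind == "single") {
        S_list[[i]] <- matrix(v1, 1L, 1L)
      } else {
        cc <- if (identical(cl$cov_label, "zero")) 0
              else par[[paste0("c.", cl$cov_label)]]
        S_list[[i]] <- matrix(c(v1, cc, cc, v2), 2L, 2L)
      }
    }
    return(list(S = S_list, G = vector("list", length(classes))))
  }
  cs <- component_sigmas(spec, par)
  if (is.null(cs)) return(NULL)
  rg <- if (spec$sex_limitation == "general" && isTRUE(spec$rg_mf_free))
    par[["rg_mf"]] else spec$rg_mf
  comps <- spec$components
  # within-person blocks per sex (identical sets when no sex limitation)
  W <- list()
  for (sx in c("F", "M")) {
    tot <- matrix(0, p, p)
    for (X in comps) tot <- tot + cs[[sx]][[X]]$S
    W[[sx]] <- tot
  }
  # relatedness classes share cross-member blocks; cache by (type, sexes)
  rho_of <- function(X, type) switch(X,
    A = switch(type, MZ = 1, DZ = 0.5, DZOS = 0.5 * rg),
    D = switch(type, MZ = 1, DZ = 0.25, DZOS = 0.25),
    C = 1, E = 0)
  K_cache <- list()
  cross_block <- function(type, s1, s2) {
    key <- paste0(type, s1, s2)
    K <- K_cache[[key]]
    if (!is.null(K)) return(K)
    K <- matrix(0, p, p)
    same_set <- s1 == s2 || spec$sex_limitation != "general"
    for (X in comps) {
      rho <- rho_of(X, type)
      if (rho == 0) next
      if (same_set) {
        K <- K + rho * cs[[s1]][[X]]$S
      } else {
        L1 <- cs[[s1]][[X]]$L; L2 <- cs[[s2]][[X]]$L
        if (is.null(L1)) {
          L1 <- chol_psd(cs[[s1]][[X]]$S); L2 <- chol_psd(cs[[s2]][[X]]$S)
        }
        K <- K + rho * (L1 %*% t(L2))
      }
    }
    K_cache[[key]] <<- K
    K
  }
  G0 <- NULL
  if (isTRUE(spec$contrast)) {
    s <- vapply(spec$traits, function(t) par[[paste0("s.", t)]], numeric(1))
    B <- matrix(0, 2L * p, 2L * p)
    for (t in seq_len(p)) {
      B[t, p + t] <- s[t]; B[p + t, t] <- s[t]
    }
    G0 <- solve(diag(2L * p) - B)
  }
  pair_cache <- list()
  S_list <- vector("list", length(classes))
  G_list <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    if (cl$kind == "single") {
      S <- W[[cl$sexes[1L]]]
    } else {
      type <- if (cl$group %in% c("MZF", "MZM")) "MZ"
              else if (cl$group == "DZOS") "DZOS" else "DZ"
      key <- paste0(type, cl$sexes[1L], cl$sexes[2L])
      S <- pair_cache[[key]]
      if (is.null(S)) {
        K <- cross_block(type, cl$sexes[1L], cl$sexes[2L])
        S <- rbind(cbind(W[[cl$sexes[1L]]], K),
                   cbind(t(K), W[[cl$sexes[2L]]]))
        if (!is.null(G0)) S <- G0 %*% S %*% t(G0)
        pair_cache[[key]] <- S
      }
      if (!is.null(G0)) G_list[[i]] <- G0
    }
    if (cl$group %in% spec$scale_groups)
      S <- S * par[[paste0("kappa.", cl$group)]]
    S_list[[i]] <- S
  }
  list(S = S_list, G = G_list)
}

chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S))
}

#' Implied pair moments of a model
#'
#' The mean vector and covariance matrix the model implies for one family
#' (slots: member 1's traits then member 2's).
#'
#' @param spec a [twin_model()] or [saturated_model()] specification.
#' @param params full named parameter vector.
#' @param group zygosity group label.
#' @param sexes member sexes (`"F"`/`"M"`); inferred from the group label
#'   where unambiguous.
#' @param covariates optional list with one named numeric vector per member.
#' @return list with `mean` (length 2p, or p for a singleton) and `cov`.
#' @export
implied_pair_moments <- function(spec, params, group, sexes = NULL,
                                 covariates = NULL) {
  params <- as.list(params)
  n_members <- if (identical(group, "singleton")) 1L else 2L
  if (is.null(sexes)) {
    sexes <- switch(group,
      MZF = c("F", "F"), MZM = c("M", "M"), DZF = c("F", "F"),
      DZM = c("M", "M"), DZOS = c("F", "M"),
      stop("sexes must be given for group ", group))
  }
  eff <- if (n_members == 2L) effective_group(group, sexes) else group
  cl <- list(kind = if (n_members == 2L) "pair" else "single",
             group = eff, sexes = sexes,
             var_label = if (spec$type == "saturated")
               spec$sat$var_classes[[eff]] else NA,
             cov_label = if (spec$type == "saturated")
               spec$sat$cov_classes[[eff]] else NA,
             mean_label = eff)
  sg <- build_sigma_list(spec, params, list(cl))
  if (is.null(sg)) stop("parameter values outside the model space")
  p <- length(spec$traits)
  mt <- mean_terms(spec, list(cl))
  mu <- numeric(n_members * p)
  for (m in seq_len(n_members)) for (t in seq_len(p)) {
    slot <- (m - 1L) * p + t
    for (tm in mt) {
      if (tm$trait != t) next
      if (!is.na(tm$member) && tm$member != m) next
      if (!is.na(tm$class_label) && tm$class_label != cl$mean_label) next
      x <- if (is.na(tm$covariate)) 1
           else covariates[[m]][[tm$covariate]]
      if (is.null(x) || is.na(x)) x <- 0
      mu[slot] <- mu[slot] + params[[tm$name]] * x
    }
  }
  if (!is.null(sg$G[[1L]])) mu <- as.numeric(sg$G[[1L]] %*% mu)
  list(mean = mu, cov = sg$S[[1L]])
}
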