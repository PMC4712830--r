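# Compiled implied-covariance builder: resolves all parameter-name lookups
# of build_sigma_list() to integer indices once per fit, so the per-
# evaluation work is pure arithmetic. The generic build_sigma_list() remains
# the reference implementation (used by fiml_neg2ll() and
# implied_pair_moments()); tests assert the two paths agree.

compile_sigma_plan <- function(spec, classes, cov_names) {
  p <- length(spec$traits)
  idx <- function(nm) {
    i <- match(nm, cov_names)
    if (anyNA(i)) stop("internal: unresolved parameter ", nm[is.na(i)][1L])
    i
  }
  sexlim <- identical(spec$sex_limitation, "general")
  cls_meta <- lapply(classes, function(cl) {
    type <- if (cl$kind == "single") 0L
            else if (cl$group %in% c("MZF", "MZM")) 1L
            else if (cl$group == "DZOS") 3L else 2L
    scale_i <- if (cl$group %in% spec$scale_groups)
      idx(paste0("kappa.", cl$group)) else 0L
    key <- if (cl$kind == "single") ""
           else if (sexlim) paste0(type, paste(cl$sexes, collapse = ""))
           else as.character(type)
    list(kind = cl$kind, type = type, sexes = cl$sexes, scale_i = scale_i,
         key = key, cl = cl)
  })
  plan <- list(p = p, classes = cls_meta, spec_type = spec$type)
  if (spec$type == "saturated") {
    plan$sat <- lapply(cls_meta, function(m) {
      cl <- m$cl
      if (isTRUE(spec$sat$symmetric)) {
        i1 <- i2 <- idx(paste0("v.", cl$var_label))
      } else {
        i1 <- idx(paste0("v.", cl$var_label, ".m1"))
        i2 <- idx(paste0("v.", cl$var_label, ".m2"))
      }
      ic <- if (cl$kind == "pair" && !identical(cl$cov_label, "zero"))
        idx(paste0("c.", cl$cov_label)) else 0L
      c(i1, i2, ic)
    })
    return(plan)
  }
  plan$components <- spec$components
  plan$param9n <- spec$parameterization
  plan$sexlim <- spec$sex_limitation == "general"
  plan$contrast <- isTRUE(spec$contrast)
  if (plan$contrast)
    plan$s_idx <- idx(paste0("s.", spec$traits))
  if (plan$param9n == "cholesky") {
    lt <- which(lower.tri(matrix(0, p, p), diag = TRUE))
    sexes <- if (plan$sexlim) c("F", "M") else ""
    plan$L_idx <- list()
    for (sx in sexes) {
      key <- if (nzchar(sx)) sx else "F"
      plan$L_idx[[key]] <- lapply(setNames(nm = spec$components), function(X) {
        pre <- if (nzchar(sx)) paste0("l.", X, ".", sx) else paste0("l.", X)
        idx(chol_names(pre, p))
      })
    }
    if (!plan$sexlim) plan$L_idx$M <- plan$L_idx$F
    plan$lt <- lt
    plan$rg_idx <- if (plan$sexlim && isTRUE(spec$rg_mf_free))
      idx("rg_mf") else 0L
    plan$rg_fixed <- spec$rg_mf
  } else {
    plan$v_idx <- idx(paste0("v.", spec$traits))
    nonE <- setdiff(spec$components, "E")
    plan$sh_idx <- lapply(setNames(nm = nonE), function(X)
      idx(paste0("sh.", X, ".", spec$traits)))
    if (p == 2L) {
      plan$r_idx <- lapply(setNames(nm = spec$components), function(X) {
        if (X == "E" && plan$param9n == "share_rp") NA_integer_
        else idx(paste0("r.", X))
      })
      if (plan$param9n == "share_rp") plan$rp_idx <- idx("rp")
    }
  }
  plan
}

# Fast evaluation: pc is the covariance-parameter vector in cov_names order.
# Returns list(S, G) or NULL for out-of-model values.
sigma_from_plan <- function(plan, pc) {
  if (any(!is.finite(pc))) return(NULL)
  p <- plan$p
  ncl <- length(plan$classes)
  S_list <- vector("list", ncl)
  G_list <- vector("list", ncl)
  if (plan$spec_type == "saturated") {
    for (i in seq_len(ncl)) {
      m <- plan$classes[[i]]
      ii <- plan$sat[[i]]
      S_list[[i]] <- if (m$kind == "single")
        matrix(pc[ii[1L]], 1L, 1L)
      else {
        cc <- if (ii[3L] == 0L) 0 else pc[ii[3L]]
        matrix(c(pc[ii[1L]], cc, cc, pc[ii[2L]]), 2L, 2L)
      }
    }
    return(list(S = S_list, G = G_list))
  }
  comps <- plan$components
  # component covariance (and factor) per sex
  CS <- list(F = NULL, M = NULL)
  CL <- list(F = NULL, M = NULL)
  if (plan$param9n == "cholesky") {
    for (sx in if (plan$sexlim) c("F", "M") else "F") {
      sl <- list(); ss <- list()
      for (X in comps) {
        L <- matrix(0, p, p)
        L[plan$lt] <- pc[plan$L_idx[[sx]][[X]]]
        sl[[X]] <- L
        ss[[X]] <- tcrossprod(L)
      }
      CL[[sx]] <- sl; CS[[sx]] <- ss
    }
    if (!plan$sexlim) { CL$M <- CL$F; CS$M <- CS$F }
    rg <- if (plan$rg_idx > 0L) pc[plan$rg_idx] else plan$rg_fixed
  } else {
    v <- pc[plan$v_idx]
    sh <- lapply(plan$sh_idx, function(ii) pc[ii])
    if (any(unlist(sh) < 0)) return(NULL)
    eshare <- 1 - Reduce(`+`, sh, rep(0, p))
    if (any(eshare < 0)) return(NULL)
    sh$E <- eshare
    rr <- list()
    if (p == 2L) {
      for (X in comps) {
        if (X == "E" && plan$param9n == "share_rp") {
          rp <- pc[plan$rp_idx]; rA <- rr$A
          den <- sqrt(sh$E[1L] * sh$E[2L])
          if (den < 1e-12) return(NULL)
          re <- (rp - rA * sqrt(sh$A[1L] * sh$A[2L])) / den
          if (abs(re) > 1) return(NULL)
          rr$E <- re
        } else rr[[X]] <- pc[plan$r_idx[[X]]]
      }
    }
    ss <- list()
    for (X in comps) {
      d <- sh[[X]] * v
      if (p == 1L) ss[[X]] <- matrix(d, 1L, 1L)
      else {
        off <- rr[[X]] * sqrt(d[1L] * d[2L])
        ss[[X]] <- matrix(c(d[1L], off, off, d[2L]), 2L, 2L)
      }
    }
    CS$F <- ss; CS$M <- ss
    rg <- 1
  }
  WF <- Reduce(`+`, CS$F)
  WM <- if (plan$sexlim) Reduce(`+`, CS$M) else WF
  W <- list(F = WF, M = WM)
  G0 <- NULL
  if (plan$contrast) {
    s <- pc[plan$s_idx]
    B <- matrix(0, 2L * p, 2L * p)
    for (t in seq_len(p)) { B[t, p + t] <- s[t]; B[p + t, t] <- s[t] }
    G0 <- solve(diag(2L * p) - B)
  }
  rho_tab <- function(X, type) switch(X,
    A = c(1, 0.5, 0.5 * rg)[type],
    D = c(1, 0.25, 0.25)[type],
    C = 1, E = 0)
  pair_cache <- list()
  for (i in seq_len(ncl)) {
    m <- plan$classes[[i]]
    if (m$kind == "single") {
      S <- W[[m$sexes[1L]]]
    } else {
      key <- m$key
      S <- pair_cache[[key]]
      if (is.null(S)) {
        K <- matrix(0, p, p)
        s1 <- m$sexes[1L]; s2 <- m$sexes[2L]
        same_set <- s1 == s2 || !plan$sexlim
        for (X in comps) {
          rho <- rho_tab(X, m$type)
          if (rho == 0) next
          K <- K + if (same_set) rho * CS[[s1]][[X]]
                   else rho * (CL[[s1]][[X]] %*% t(CL[[s2]][[X]]))
        }
        S <- rbind(cbind(W[[s1]], K), cbind(t(K), W[[s2]]))
        if (!is.null(G0)) S <- G0 %*% S %*% t(G0)
        pair_cache[[key]] <- S
      }
      if (!is.null(G0)) G_list[[i]] <- G0
    }
    if (m$scale_i > 0L) S <- S * pc[m$scale_i]
    S_list[[i]] <- S
  }
  list(S = S_list, G = G_list)
}
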