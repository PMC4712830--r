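# Shared fixtures: small generating configs and an independent multivariate
# normal log-density used as the FIML oracle.

# Independent -2 log-density oracle (direct solve/determinant, no Cholesky
# pattern grouping shared with the package kernel).
oracle_neg2ll <- function(y, mu, S) {
  k <- length(y)
  r <- y - mu
  k * log(2 * pi) + as.numeric(determinant(S, logarithm = TRUE)$modulus) +
    as.numeric(t(r) %*% solve(S) %*% r)
}

# Tiny univariate AE config for fast tests.
small_ae_config <- function(h2 = 0.4, v = 1, n = c(MZF = 40, MZM = 20,
                                                   DZF = 30, DZM = 15,
                                                   DZOS = 25, SIB = 5),
                            n_singletons = 10L, beta_sex = 0,
                            trait = "hm_log") {
  b <- matrix(beta_sex, 1L, 1L, dimnames = list(trait, "sex_male"))
  generating_config(
    trait, n, n_singletons = n_singletons,
    sigma = list(A = matrix(h2 * v), E = matrix((1 - h2) * v)),
    mean = list(intercept = setNames(0, trait), beta = b),
    name = "small-ae")
}

# Bivariate AE config with known rg/re.
small_biv_config <- function(rg = 0.5, re = 0.2, h2 = c(0.4, 0.6),
                             v = c(1, 1),
                             n = c(MZF = 60, MZM = 30, DZF = 40, DZM = 20,
                                   DZOS = 30, SIB = 0),
                             n_singletons = 0L) {
  a2 <- h2 * v; e2 <- (1 - h2) * v
  A <- diag(a2); A[1, 2] <- A[2, 1] <- rg * sqrt(prod(a2))
  E <- diag(e2); E[1, 2] <- E[2, 1] <- re * sqrt(prod(e2))
  generating_config(
    c("hm_log", "swan_mi"), n, n_singletons = n_singletons,
    sigma = list(A = A, E = E),
    mean = list(intercept = c(hm_log = 0, swan_mi = 0),
                beta = matrix(0, 2, 0,
                              dimnames = list(c("hm_log", "swan_mi"), NULL))),
    name = "small-biv")
}

zero_series <- function(n = 150L, subject_id = "zero") {
  rigid_motion_series(subject_id, matrix(0, n, 3), matrix(0, n, 3))
}
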