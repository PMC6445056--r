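# Independent naive implementations used as oracles: explicit per-site
# loops and closed-form normal equations, written without reference to the
# package internals.

oracle_fst <- function(fa, fb, na = NULL, nb = NULL, estimator = "wright") {
  num <- 0; den <- 0
  for (i in seq_along(fa)) {
    if (is.na(fa[i]) || is.na(fb[i])) next
    if (estimator == "wright") {
      p <- (fa[i] + fb[i]) / 2
      ht <- 2 * p * (1 - p)
      hs <- (2 * fa[i] * (1 - fa[i]) + 2 * fb[i] * (1 - fb[i])) / 2
      num <- num + (ht - hs); den <- den + ht
    } else {
      if (is.na(na[i]) || is.na(nb[i]) || na[i] <= 1 || nb[i] <= 1) next
      num <- num + (fa[i] - fb[i])^2 -
        fa[i] * (1 - fa[i]) / (na[i] - 1) - fb[i] * (1 - fb[i]) / (nb[i] - 1)
      den <- den + fa[i] * (1 - fb[i]) + fb[i] * (1 - fa[i])
    }
  }
  if (den == 0) NA_real_ else num / den
}

oracle_dxy <- function(fx, fy, mode = "per_site") {
  ok <- !is.na(fx) & !is.na(fy)
  fx <- fx[ok]; fy <- fy[ok]
  if (!length(fx)) return(NA_real_)
  if (mode == "per_site") {
    tot <- 0
    for (i in seq_along(fx)) {
      tot <- tot + fx[i] * (1 - fy[i]) + fy[i] * (1 - fx[i])
    }
    tot / length(fx)
  } else {
    sx_maj <- 0; sx_min <- 0; sy_maj <- 0; sy_min <- 0
    for (i in seq_along(fx)) {
      sx_maj <- sx_maj + fx[i]; sx_min <- sx_min + (1 - fx[i])
      sy_maj <- sy_maj + fy[i]; sy_min <- sy_min + (1 - fy[i])
    }
    sx_maj * sy_min + sy_maj * sx_min
  }
}

oracle_hp <- function(f_major) {
  f_major <- f_major[!is.na(f_major)]
  if (!length(f_major)) return(NA_real_)
  s1 <- 0; s2 <- 0
  for (f in f_major) {
    s1 <- s1 + f; s2 <- s2 + (1 - f)
  }
  2 * s1 * s2 / (s1 + s2)^2
}

# Closed-form OLS for the coefficient of the first non-intercept column.
oracle_ols <- function(y, X) {
  X <- cbind(1, X)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  t_stat <- beta / se
  list(beta = unname(beta[2]), se = unname(se[2]), t = unname(t_stat[2]),
       p = unname(2 * pt(-abs(t_stat[2]), df)))
}

random_afreq_fixture <- function(n_sites, seed) {
  set.seed(seed)
  list(fm = runif(n_sites), ft = runif(n_sites), fe = runif(n_sites),
       nm = sample(seq(10, 60, 2), n_sites, TRUE),
       nt = sample(seq(10, 60, 2), n_sites, TRUE),
       ne = sample(seq(10, 60, 2), n_sites, TRUE))
}

fixture_path <- function(...) testthat::test_path("fixtures", ...)

new_manifest_for_test <- function(x) {
  tailsweep:::new_manifest(data.frame(sample = names(x),
                                      population = unname(x),
                                      stringsAsFactors = FALSE))
}
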