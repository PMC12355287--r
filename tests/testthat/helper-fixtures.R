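# Small builders used across test files.  Everything is generated in
# code; no stored fixtures.

# two-year panel for a handful of zips and a few constituents
toy_panel <- function(zips = c("01002", "10001", "90210"),
                      years = c(2005L, 2006L),
                      constituents = c("SO4", "Ni", "OC"),
                      seed = 42L) {
  set.seed(seed)
  grid <- expand.grid(zip = zips, year = years,
                      stringsAsFactors = FALSE)
  for (cc in constituents)
    grid[[cc]] <- round(runif(nrow(grid), 0.5, 20), 3)
  as_constituent_panel(grid)
}

toy_cohort <- function(n = 5L, zips = c("01002", "10001", "90210"),
                       tx_year = 2006L, seed = 7L) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             zip = sample(zips, n, replace = TRUE),
             tx_year = rep(tx_year, n),
             tx_month = sample.int(12L, n, replace = TRUE))
}

# iid decile matrix plus logistic outcome with known coefficients
toy_decile_data <- function(n, J, w, beta1, beta0 = -1, seed = 1L) {
  set.seed(seed)
  D <- matrix(sample(0:9, n * J, replace = TRUE), n, J,
              dimnames = list(NULL, paste0("x", seq_len(J))))
  eta <- beta0 + beta1 * drop(D %*% w)
  list(D = D, y = rbinom(n, 1L, plogis(eta)))
}

# exhaustive simplex grid search oracle for the constrained GLM: for
# every weight vector on a step-resolution grid, profile out the
# unconstrained coefficients with an ordinary logistic fit and keep the
# best log-likelihood
grid_oracle_loglik <- function(D, y, step = 0.02) {
  k <- round(1 / step)
  best <- -Inf
  for (a in 0:k) for (b in 0:(k - a)) {
    w <- c(a, b, k - a - b) / k
    idx <- drop(D %*% w)
    f <- suppressWarnings(
      glm.fit(cbind(1, idx), y, family = binomial()))
    ll <- -f$deviance / 2
    if (ll > best) best <- ll
  }
  best
}

# truncated-power-basis natural cubic spline (independent of
# splines::ns); columns: x, then d_k(x) - d_{K-1}(x) for the standard
# natural-spline construction over all knots (boundary included)
tp_natural_spline <- function(x, knots_all) {
  K <- length(knots_all)
  d <- function(k) {
    (pmax(x - knots_all[k], 0)^3 - pmax(x - knots_all[K], 0)^3) /
      (knots_all[K] - knots_all[k])
  }
  cols <- list(x)
  for (k in seq_len(K - 2L)) cols[[k + 1L]] <- d(k) - d(K - 1L)
  do.call(cbind, cols)
}
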