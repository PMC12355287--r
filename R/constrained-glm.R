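# Stable softplus: log(1 + exp(eta)) without overflow.
softplus <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

#' Simplex-constrained weighted quantile sum GLM
#'
#' Maximizes the Bernoulli log-likelihood of a logistic model
#' \deqn{logit P(Y = 1) = \beta_0 + \beta_1 \sum_i w_i d_i + \gamma' Z}
#' jointly over the constituent weights \eqn{w} on the probability
#' simplex (non-negative, summing to 1) and the unconstrained
#' coefficients.  The same likelihood serves binary outcomes (one row
#' per subject) and discrete-time survival (one row per person-period,
#' with the spline basis for time included in \code{Z}).
#'
#' The problem is solved on the product scale \eqn{c_i = \beta_1 w_i}:
#' with \eqn{w} on the simplex and \eqn{\beta_1} free, the constraint
#' is exactly that the \eqn{c_i} are either all non-negative or all
#' non-positive.  Each sign branch is a box-constrained logistic
#' likelihood maximized by L-BFGS-B with analytic gradients (so corner
#' solutions with some \eqn{w_i = 0} are attained exactly), with
#' several restarts per branch; the better branch wins and
#' \eqn{w = c/\sum c}, \eqn{\beta_1 = \sum c}.  When \eqn{\beta_1 = 0}
#' the weights are not identified; a uniform vector is returned with
#' the (still maximal) likelihood.
#'
#' @param D integer matrix of quantile scores, one column per
#'   constituent.
#' @param y binary response vector (0/1), length \code{nrow(D)}.
#' @param Z optional numeric covariate matrix (no intercept column).
#' @param n_starts maximum optimizer attempts per sign branch: the
#'   warm start plus up to \code{n_starts - 1} perturbed restarts,
#'   used only when the previous attempt fails to converge (each
#'   branch is convex, so a converged attempt is the branch optimum).
#' @param tol relative convergence tolerance on the objective.
#' @param seed optional integer seed for the random restarts.
#' @param maxit maximum BFGS iterations per start.
#' @return list with \code{w} (simplex weights), \code{beta0},
#'   \code{beta1}, \code{gamma}, \code{loglik}, and \code{converged}.
#' @export
fit_constrained_glm <- function(D, y, Z = NULL, n_starts = 5L,
                                tol = 1e-8, seed = NULL, maxit = 2000L) {
  D <- as.matrix(D)
  storage.mode(D) <- "double"
  y <- as.numeric(y)
  n <- nrow(D); J <- ncol(D)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
    stopifnot(nrow(Z) == n)
  }
  p <- if (is.null(Z)) 0L else ncol(Z)

  # standardize covariates internally: L-BFGS-B converges poorly when
  # column scales differ by orders of magnitude; coefficients are
  # mapped back to the original scale on exit
  if (p) {
    z_mu <- colMeans(Z)
    z_sd <- apply(Z, 2L, stats::sd)
    z_sd[!is.finite(z_sd) | z_sd < 1e-12] <- 1
    Z <- sweep(sweep(Z, 2L, z_mu), 2L, z_sd, "/")
  }

  if (J == 1L) {
    # simplex of dimension 0: the weight is identically 1
    df <- data.frame(y = y, index = D[, 1])
    f <- if (p) glm(y ~ ., data = cbind(df, as.data.frame(Z)),
                    family = binomial())
         else glm(y ~ index, data = df, family = binomial())
    cf <- coef(f)
    return(list(w = setNames(1, colnames(D)), beta0 = unname(cf[1]),
                beta1 = unname(cf[2]),
                gamma = if (p) unname(cf[-(1:2)]) else numeric(0),
                loglik = as.numeric(stats::logLik(f)),
                converged = f$converged))
  }

  # par = (b0, c_1..c_J, gamma) on the product scale c = beta1 * w
  negll <- function(par) {
    eta <- par[1L] + drop(D %*% par[2L:(J + 1L)])
    if (p) eta <- eta + drop(Z %*% par[(J + 2L):(J + 1L + p)])
    -sum(y * eta - softplus(eta))
  }
  neggr <- function(par) {
    eta <- par[1L] + drop(D %*% par[2L:(J + 1L)])
    if (p) eta <- eta + drop(Z %*% par[(J + 2L):(J + 1L + p)])
    r <- y - plogis(eta)
    -c(sum(r), drop(crossprod(D, r)), if (p) drop(crossprod(Z, r)))
  }

  # warm start: crude working-response least squares on (1, D, Z)
  X0 <- cbind(1, D, Z)
  cf0 <- tryCatch(qr.coef(qr(X0), qlogis((y + 0.5) / 2)),
                  error = function(e) rep(0, ncol(X0)))
  cf0[is.na(cf0)] <- 0
  b0_0 <- cf0[1L]; c_0 <- cf0[2L:(J + 1L)]
  g_0 <- if (p) cf0[(J + 2L):(J + 1L + p)] else numeric(0)

  perturb <- matrix(0, max(n_starts - 1L, 0L), J)
  if (n_starts > 1L) {
    rng_state <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    if (!is.null(seed)) set.seed(derive_seed(seed, "start"))
    perturb[] <- abs(rnorm(length(perturb), 0, 0.05))
    if (!is.null(seed) && !is.null(rng_state))
      assign(".Random.seed", rng_state, globalenv())
  }

  # each sign branch is a convex program (concave log-likelihood over a
  # box), so one warm start suffices; perturbed restarts are used only
  # if L-BFGS-B reports failure
  best <- NULL
  any_conv <- FALSE
  for (sign_branch in c(1, -1)) {
    c_base <- pmax(sign_branch * c_0, 0) * sign_branch
    lower <- c(-Inf, if (sign_branch > 0) rep(0, J) else rep(-Inf, J),
               rep(-Inf, p))
    upper <- c(Inf, if (sign_branch > 0) rep(Inf, J) else rep(0, J),
               rep(Inf, p))
    branch_conv <- FALSE
    for (s in seq_len(n_starts)) {
      cs <- if (s == 1L) c_base
            else c_base + sign_branch * perturb[s - 1L, ]
      st <- c(b0_0, cs, g_0)
      fit <- tryCatch(
        stats::optim(st, negll, neggr, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = maxit, lmm = 20L,
                                    factr = max(1, tol * 1e12))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        if (fit$convergence == 0L) branch_conv <- TRUE
        if (is.null(best) || fit$value < best$value) best <- fit
      }
      if (branch_conv) break
    }
    any_conv <- any_conv || branch_conv
  }
  if (is.null(best)) return(list(converged = FALSE))
  cc <- best$par[2L:(J + 1L)]
  b1 <- sum(cc)
  w <- if (abs(b1) > 1e-12) cc / b1 else rep(1 / J, J)
  # guard against L-BFGS-B round-off just outside the box
  w <- pmax(w, 0); w <- w / sum(w)
  g_std <- if (p) best$par[(J + 2L):(J + 1L + p)] else numeric(0)
  g_raw <- if (p) g_std / z_sd else numeric(0)
  b0_raw <- best$par[1L] - if (p) sum(g_std * z_mu / z_sd) else 0
  list(w = setNames(w, colnames(D)), beta0 = unname(b0_raw), beta1 = b1,
       gamma = g_raw, loglik = -best$value, converged = any_conv)
}

#' Bootstrap estimation of simplex-constrained mixture weights
#'
#' Draws \code{B} subject-level resamples (with replacement) of the
#' training split, fits the simplex-constrained GLM on each, and
#' returns the unweighted mean of the converged weight vectors,
#' renormalized to sum to one.  For person-period data, resampling is
#' clustered: a resampled recipient contributes all of their rows.
#'
#' @inheritParams fit_constrained_glm
#' @param B number of bootstrap resamples.
#' @param cluster vector identifying the subject each row belongs to;
#'   defaults to one subject per row.
#' @param seed integer seed governing the resampling and restart
#'   streams.
#' @return list with \code{w} (mean weights on the simplex),
#'   \code{n_boot_used} (count of converged fits), \code{B}, and the
#'   matrix \code{w_boot} of per-resample weights.
#' @export
estimate_bootstrap_weights <- function(D, y, Z = NULL, B = 100L,
                                       cluster = NULL, seed = 1L,
                                       n_starts = 5L, tol = 1e-8) {
  D <- as.matrix(D)
  if (B < 1L) stop("B must be at least 1")
  n <- nrow(D)
  if (is.null(cluster)) cluster <- seq_len(n)
  rows_of <- split(seq_len(n), cluster)
  ncl <- length(rows_of)
  W <- matrix(NA_real_, B, ncol(D), dimnames = list(NULL, colnames(D)))
  rng_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, globalenv()))
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, "bootstrap", b))
    cl <- sample.int(ncl, ncl, replace = TRUE)
    rows <- unlist(rows_of[cl], use.names = FALSE)
    fit <- fit_constrained_glm(D[rows, , drop = FALSE], y[rows],
                               if (is.null(Z)) NULL else
                                 Z[rows, , drop = FALSE],
                               n_starts = n_starts, tol = tol,
                               seed = derive_seed(seed, "start", b))
    if (isTRUE(fit$converged)) W[b, ] <- fit$w
  }
  used <- which(!is.na(W[, 1L]))
  if (!length(used))
    stop("all ", B, " bootstrap fits failed to converge")
  if (length(used) < B)
    message(B - length(used), " of ", B,
            " bootstrap fits did not converge and were skipped")
  w <- colMeans(W[used, , drop = FALSE])
  w <- pmax(w, 0)
  w <- w / sum(w)
  list(w = w, n_boot_used = length(used), B = B,
       w_boot = W[used, , drop = FALSE])
}
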