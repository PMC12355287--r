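#' Two-stage weighted quantile sum regression
#'
#' Fits the full WQS pipeline to a cohort table: decile-transforms the
#' mixture columns (cut points computed once on the full sample),
#' splits recipients into training and validation sets, estimates
#' simplex-constrained constituent weights by bootstrap on the training
#' split, and regresses the outcome on the frozen mixture index
#' \eqn{wqs = \sum_i w_i d_i} in the validation split.
#'
#' Binary outcomes (e.g. delayed graft function, first-year acute
#' rejection) use a logistic link; the mixture coefficient is reported
#' as an adjusted odds ratio and as the percent increase in the odds
#' per one-decile increase in the whole mixture.  Time-to-event
#' outcomes, written as \code{survival::Surv(months, event)} on the
#' left-hand side, use pooled logistic regression over person-month
#' records with a natural-spline baseline hazard — a discrete-time
#' approximation to the Cox model — and report an adjusted hazard
#' ratio.  Stage-1 weight estimation adjusts for the same covariates
#' (and, for survival outcomes, the same spline-in-time terms) as
#' stage 2.
#'
#' @param formula model formula.  The right-hand side lists the
#'   covariates to adjust for; the left-hand side is a binary outcome
#'   column or a \code{Surv(months, event)} expression.  The mixture
#'   components are given separately via \code{mixture}, not in the
#'   formula.
#' @param data data frame with one row per recipient: the outcome, the
#'   covariates and one numeric concentration column per mixture
#'   component (e.g. the output of \code{\link{link_exposures}} merged
#'   onto the cohort table).
#' @param mixture character vector naming the mixture component
#'   columns.
#' @param q number of quantile groups (10 = deciles, so effects are per
#'   one-decile increase).
#' @param B number of bootstrap resamples for stage-1 weight
#'   estimation.
#' @param train_fraction fraction of recipients assigned to the
#'   training split.
#' @param family \code{"binomial"} or \code{"pooled-logistic"};
#'   inferred from the formula when omitted.
#' @param spline_df degrees of freedom of the baseline-hazard spline
#'   (survival outcomes only).
#' @param max_months administrative censoring horizon in months.
#' @param horizon optional follow-up truncation for sensitivity
#'   analysis (e.g. 12 restricts to the first post-transplant year).
#' @param n_starts optimizer restarts per bootstrap fit.
#' @param seed integer seed; fans out deterministically to the split,
#'   bootstrap and restart streams.
#' @param stage1_adjust adjust stage-1 fits for the covariates
#'   (default TRUE; FALSE estimates weights from the mixture alone).
#' @param fixed_weights optional named simplex weight vector.  When
#'   supplied, stage 1 is skipped entirely (no split, no bootstrap):
#'   the weights are frozen as given and the stage-2 model is fit on
#'   the full sample.  Used to apply externally estimated weights to a
#'   new cohort, or known ground-truth weights in simulation studies.
#' @return an object of class \code{"wqs"} with components including
#'   \code{weights} (simplex constituent weights), \code{beta1},
#'   \code{ci95}, \code{percent_increase}, \code{coefficients},
#'   \code{vcov}, \code{n_boot_used} and the frozen decile cut points.
#'   Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{confint}, \code{weights}, \code{plot}, \code{predict}.
#' @examples
#' sim <- simulate_wqs_cohort(sim_config(n_recipients = 400, B = 10))
#' dat <- wqs_analysis_table(sim)
#' f <- wqs(dgf ~ age + sex, data = dat, mixture = sim$config$constituents,
#'          B = 10, seed = 7)
#' print(f)
#' @export
wqs <- function(formula, data, mixture, q = 10L, B = 100L,
                train_fraction = 0.4, family = NULL, spline_df = 4L,
                max_months = 60L, horizon = NULL, n_starts = 5L,
                seed = 1L, stage1_adjust = TRUE, fixed_weights = NULL) {
  cl <- match.call()
  stopifnot(is.data.frame(data), all(mixture %in% names(data)))
  lhs <- formula[[2L]]
  yval <- eval(lhs, data, environment(formula))
  is_surv <- inherits(yval, "Surv")
  if (is.null(family))
    family <- if (is_surv) "pooled-logistic" else "binomial"
  family <- match.arg(family, c("binomial", "pooled-logistic"))
  if (family == "pooled-logistic" && !is_surv)
    stop("pooled-logistic outcomes must be written as Surv(months, event)")
  if (family == "binomial" && is_surv)
    stop("binary family cannot take a Surv() outcome")

  # covariate design matrix (handles factors); drop intercept column
  rhs <- stats::reformulate(attr(terms(formula, data = data), "term.labels"),
                            intercept = TRUE)
  Zmat <- model.matrix(rhs, data = data)
  Zmat <- Zmat[, -1L, drop = FALSE]
  n <- nrow(data)
  if (nrow(Zmat) != n)
    stop("missing values in covariates are not supported; ",
         "complete cases only")

  # deciles on the full analysis sample so both splits share cut points
  expo <- data.frame(id = seq_len(n), data[, mixture, drop = FALSE],
                     check.names = FALSE)
  dec <- quantile_transform(expo, q = q)
  D <- as.matrix(dec[, mixture, drop = FALSE])

  if (is.null(fixed_weights)) {
    sp <- split_cohort(seq_len(n), train_fraction = train_fraction,
                       seed = seed)
    tr <- sp$train
    va <- sp$validation
  } else {
    if (is.null(names(fixed_weights)) ||
        !setequal(names(fixed_weights), mixture))
      stop("fixed_weights must be named after the mixture components")
    fixed_weights <- fixed_weights[mixture]
    if (any(fixed_weights < 0) || abs(sum(fixed_weights) - 1) > 1e-8)
      stop("fixed_weights must be non-negative and sum to 1")
    sp <- NULL
    tr <- integer(0)
    va <- seq_len(n)
  }
  fixed_bw <- list(w = fixed_weights, n_boot_used = 0L, B = 0L,
                   w_boot = NULL)

  if (family == "binomial") {
    y <- as.numeric(yval)
    if (!all(y %in% c(0, 1))) stop("binary outcome must be coded 0/1")
    bw <- if (is.null(fixed_weights)) estimate_bootstrap_weights(
      D[tr, , drop = FALSE], y[tr],
      Z = if (stage1_adjust && ncol(Zmat)) Zmat[tr, , drop = FALSE] else NULL,
      B = B, seed = seed, n_starts = n_starts) else fixed_bw
    w <- bw$w
    wqs_val <- mixture_index(D[va, , drop = FALSE], w)
    s2dat <- data.frame(wqs = wqs_val,
                        Zmat[va, , drop = FALSE], check.names = FALSE)
    s2dat <- cbind(.y = y[va], s2dat)
    fit2 <- glm(.y ~ ., data = s2dat, family = binomial())
    if (!fit2$converged)
      warning("validation GLM did not converge; possible separation ",
              "— consider collapsing sparse covariates")
    cf <- coef(fit2); V <- vcov(fit2)
    b1 <- unname(cf["wqs"]); se1 <- sqrt(V["wqs", "wqs"])
    n_events <- sum(y[va]); n_periods <- length(va)
    extra <- list()
  } else {
    months <- as.integer(yval[, 1L]); event <- as.integer(yval[, 2L])
    fu <- data.frame(id = seq_len(n), months = months, event = event,
                     Zmat, check.names = FALSE)
    ppt <- expand_person_periods(fu, max_months = max_months)
    if (!is.null(horizon)) ppt <- truncate_followup(ppt, horizon)
    S <- natural_spline_basis(ppt$t, df = spline_df,
                              event_times = ppt$t[ppt$Y == 1L])
    zcols <- colnames(Zmat)
    ppt_tr <- ppt[ppt$id %in% tr, , drop = FALSE]
    S_tr <- S[ppt$id %in% tr, , drop = FALSE]
    bw <- if (is.null(fixed_weights)) {
      Z1 <- cbind(if (stage1_adjust && length(zcols))
                    as.matrix(ppt_tr[, zcols, drop = FALSE]), S_tr)
      estimate_bootstrap_weights(
        D[ppt_tr$id, , drop = FALSE], ppt_tr$Y, Z = Z1, B = B,
        cluster = ppt_tr$id, seed = seed, n_starts = n_starts)
    } else fixed_bw
    w <- bw$w
    ppt_va <- ppt[ppt$id %in% va, , drop = FALSE]
    ppt_va$wqs <- mixture_index(D[ppt_va$id, , drop = FALSE], w)
    fit2 <- fit_pooled_logistic(ppt_va, exposure = "wqs",
                                covariates = zcols,
                                spline_df = spline_df)
    cf <- fit2$coefficients; V <- fit2$vcov
    b1 <- fit2$beta1; se1 <- fit2$se
    n_events <- fit2$n_events; n_periods <- fit2$n_periods
    extra <- list(spline_df = spline_df, knots = fit2$knots,
                  boundary = fit2$boundary, max_months = max_months,
                  horizon = horizon)
  }

  zq <- qnorm(0.975)
  ci <- b1 + c(-1, 1) * zq * se1
  s2 <- data.frame(id = va,
                   data[va, setdiff(names(data), mixture), drop = FALSE],
                   row.names = NULL, check.names = FALSE)
  out <- c(list(
    call = cl, family = family, mixture = mixture, q = as.integer(q),
    weights = w, n_boot_used = bw$n_boot_used, B = B,
    w_boot = bw$w_boot,
    beta1 = b1, se = se1, ci95 = ci,
    effect = exp(b1), effect_ci95 = exp(ci),
    percent_increase = 100 * (exp(b1) - 1),
    percent_increase_ci95 = 100 * (exp(ci) - 1),
    coefficients = cf, vcov = V,
    n = n, n_train = length(tr), n_validation = length(va),
    n_events = n_events, n_periods = n_periods,
    split = sp, validation_ids = va,
    cuts = attr(dec, "cuts"), seed = seed,
    covariate_names = colnames(Zmat),
    stage2_data = s2,
    Z_validation = Zmat[va, , drop = FALSE],
    ppt_validation = if (family == "pooled-logistic") ppt_va else NULL,
    wqs_validation = if (family == "binomial") wqs_val else NULL,
    outcome = if (family == "binomial") yval else NULL,
    surv = if (family == "pooled-logistic")
      cbind(months = as.integer(yval[, 1L]),
            event = as.integer(yval[, 2L])) else NULL,
    deciles = D), extra)
  class(out) <- "wqs"
  out
}

#' @export
print.wqs <- function(x, ...) {
  cat("Weighted quantile sum regression (", x$family, ")\n", sep = "")
  cat(sprintf("  n = %d (%d train / %d validation), %d-quantile scores\n",
              x$n, x$n_train, x$n_validation, x$q))
  cat(sprintf("  stage-1 bootstraps used: %d of %d\n",
              x$n_boot_used, x$B))
  lab <- if (x$family == "binomial") "aOR" else "aHR"
  cat(sprintf("  %s per 1-decile increase in the mixture: %.4f (95%% CI %.4f-%.4f)\n",
              lab, x$effect, x$effect_ci95[1], x$effect_ci95[2]))
  cat(sprintf("  percent increase: %.1f%% (95%% CI %.1f%%-%.1f%%)\n",
              x$percent_increase, x$percent_increase_ci95[1],
              x$percent_increase_ci95[2]))
  top <- sort(x$weights, decreasing = TRUE)[1:min(3, length(x$weights))]
  cat("  top constituent weights: ",
      paste(sprintf("%s %.1f%%", names(top), 100 * top),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.wqs <- function(object, ...) object$coefficients

#' @export
vcov.wqs <- function(object, ...) object$vcov

#' Constituent weights of a WQS fit
#'
#' @param object a \code{wqs} fit.
#' @param ... unused.
#' @return named simplex weight vector (relative importance of each
#'   constituent in the mixture index).
#' @export
weights.wqs <- function(object, ...) object$weights

#' @export
confint.wqs <- function(object, parm = "wqs", level = 0.95, ...) {
  cf <- object$coefficients
  if (identical(parm, "wqs")) {
    z <- qnorm(1 - (1 - level) / 2)
    ci <- object$beta1 + c(-1, 1) * z * object$se
    m <- matrix(ci, 1, 2,
                dimnames = list("wqs", c("lower", "upper")))
    return(m)
  }
  se <- sqrt(diag(object$vcov))[parm]
  z <- qnorm(1 - (1 - level) / 2)
  cbind(lower = cf[parm] - z * se, upper = cf[parm] + z * se)
}

#' @export
summary.wqs <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  cf <- object$coefficients
  tab <- cbind(Estimate = cf, `Std. Error` = se, z = cf / se,
               `Pr(>|z|)` = 2 * pnorm(-abs(cf / se)))
  out <- list(fit = object, coefficients = tab,
              weight_table = weight_table(object))
  class(out) <- "summary.wqs"
  out
}

#' @export
print.summary.wqs <- function(x, ...) {
  print(x$fit)
  cat("\nConstituent relative importance (%):\n")
  print(x$weight_table, row.names = FALSE, digits = 3)
  cat("\nStage-2 coefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' Relative-importance bar chart of a WQS fit
#'
#' Plots each constituent's estimated share of the mixture index as a
#' percentage, in descending order.
#'
#' @param x a \code{wqs} fit.
#' @param threshold reference line often used to flag constituents
#'   contributing more than chance (1/J); set NULL to omit.
#' @param ... passed to \code{barplot}.
#' @export
plot.wqs <- function(x, threshold = 1 / length(x$weights), ...) {
  w <- sort(x$weights, decreasing = TRUE)
  bp <- barplot(100 * w, las = 2,
                ylab = "Relative importance (%)",
                main = "Estimated constituent contributions", ...)
  if (!is.null(threshold)) abline(h = 100 * threshold, lty = 2)
  invisible(bp)
}

#' Predict from a WQS fit
#'
#' Scores new exposure data with the frozen decile cut points and
#' stage-1 weights, returning the mixture index or (for binary fits)
#' the stage-2 linear predictor or event probability.
#'
#' @param object a \code{wqs} fit.
#' @param newdata data frame containing the mixture columns (and, for
#'   \code{type != "index"}, the covariate columns).
#' @param type \code{"index"}, \code{"link"} or \code{"response"}.
#' @param ... unused.
#' @export
predict.wqs <- function(object, newdata,
                        type = c("index", "link", "response"), ...) {
  type <- match.arg(type)
  expo <- data.frame(id = seq_len(nrow(newdata)),
                     newdata[, object$mixture, drop = FALSE],
                     check.names = FALSE)
  dec <- quantile_transform(expo, q = object$q, cuts = object$cuts)
  idx <- mixture_index(dec, object$weights)
  if (type == "index") return(idx)
  if (object$family != "binomial")
    stop("link/response predictions are only defined for binary fits")
  cf <- object$coefficients
  X <- cbind(`(Intercept)` = 1, wqs = idx)
  if (length(object$covariate_names)) {
    rhs <- stats::reformulate(attr(terms(eval(object$call$formula),
                                         data = newdata), "term.labels"))
    Z <- model.matrix(rhs, data = newdata)[, -1L, drop = FALSE]
    X <- cbind(X, Z[, object$covariate_names, drop = FALSE])
  }
  eta <- drop(X[, names(cf), drop = FALSE] %*% cf)
  if (type == "link") eta else plogis(eta)
}

#' Weight table in reporting form
#'
#' @param fit a \code{wqs} fit (or a named simplex weight vector).
#' @return data frame with constituent, weight, and relative importance
#'   in percent (rounded to 0.1, descending); percentages sum to 100
#'   within rounding.
#' @export
weight_table <- function(fit) {
  w <- if (inherits(fit, "wqs")) fit$weights else fit
  w <- sort(w, decreasing = TRUE)
  data.frame(constituent = names(w), weight = as.numeric(w),
             importance_pct = round(100 * as.numeric(w), 1),
             row.names = NULL)
}
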