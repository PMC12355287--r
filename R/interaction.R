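#' Effect-measure modification via an interaction term
#'
#' Refits the stage-2 model of a WQS analysis with a binary modifier's
#' main effect and its product with the mixture index added, keeping
#' the stage-1 weights frozen.  The reference-level (modifier = 0)
#' mixture effect is \eqn{exp(\beta_1)}; the modifier = 1 effect is
#' \eqn{exp(\beta_1 + \beta_{int})}, with its confidence interval from
#' the coefficient covariance; the interaction is tested with a Wald
#' test on \eqn{\beta_{int}}.  By construction the subgroup-1 log
#' effect minus the subgroup-0 log effect equals the fitted interaction
#' coefficient exactly.
#'
#' @param fit a \code{\link{wqs}} fit.
#' @param modifier name of a binary (0/1, logical, or two-level factor)
#'   column of the original data; it must vary within the validation
#'   split.
#' @param values optional explicit modifier values (one per row of the
#'   original data, indexed by recipient id) for dichotomies derived on
#'   the fly, e.g. age at transplant >= 55 or cold ischemia time > 12
#'   hours; \code{modifier} is then just a label.
#' @return object of class \code{wqs_interaction}: a \code{subgroups}
#'   table (per-level estimate with 95\% CI on the odds/hazard-ratio
#'   scale), \code{beta_int}, \code{p_interaction}, and the refitted
#'   coefficient vector and covariance.
#' @export
wqs_interaction <- function(fit, modifier, values = NULL) {
  stopifnot(inherits(fit, "wqs"), is.character(modifier),
            length(modifier) == 1L)
  s2 <- fit$stage2_data
  if (is.null(values)) {
    if (!modifier %in% names(s2))
      stop("modifier column not found in the analysis data: ", modifier)
    mv <- s2[[modifier]]
  } else {
    mv <- values[s2$id]
  }
  if (is.factor(mv)) {
    if (nlevels(droplevels(mv)) != 2L)
      stop("modifier must have exactly two levels")
    mv <- as.integer(mv == levels(droplevels(mv))[2L])
  } else mv <- as.integer(as.logical(as.numeric(mv)))
  if (length(unique(mv)) < 2L)
    stop("modifier '", modifier, "' is constant in the validation set")

  zcols <- fit$covariate_names
  # a covariate reused verbatim as the modifier would enter twice; a
  # derived dichotomy (explicit values) keeps its continuous parent
  keep_z <- if (is.null(values)) setdiff(zcols, modifier) else zcols
  if (fit$family == "binomial") {
    dat <- data.frame(.y = as.numeric(fit$outcome)[fit$validation_ids],
                      wqs = fit$wqs_validation, .mod = mv,
                      fit$Z_validation[, keep_z, drop = FALSE],
                      check.names = FALSE)
    f <- glm(.y ~ wqs * .mod + ., data = dat, family = binomial())
  } else {
    ppt <- fit$ppt_validation
    mod_by_id <- setNames(mv, s2$id)
    S <- natural_spline_basis(ppt$t, df = fit$spline_df,
                              knots = fit$knots,
                              boundary = fit$boundary)
    dat <- data.frame(.y = ppt$Y, wqs = ppt$wqs,
                      .mod = as.integer(mod_by_id[as.character(ppt$id)]),
                      ppt[, keep_z, drop = FALSE],
                      as.data.frame(S), check.names = FALSE)
    f <- glm(.y ~ wqs * .mod + ., data = dat, family = binomial())
  }
  cf <- coef(f); V <- vcov(f)
  int_name <- "wqs:.mod"
  b1 <- unname(cf["wqs"]); bint <- unname(cf[int_name])
  v11 <- V["wqs", "wqs"]; v22 <- V[int_name, int_name]
  v12 <- V["wqs", int_name]
  se0 <- sqrt(v11)
  se1 <- sqrt(v11 + v22 + 2 * v12)
  se_int <- sqrt(v22)
  z <- qnorm(0.975)
  subgroups <- data.frame(
    level = c(0L, 1L),
    log_estimate = c(b1, b1 + bint),
    estimate = exp(c(b1, b1 + bint)),
    lower = exp(c(b1 - z * se0, b1 + bint - z * se1)),
    upper = exp(c(b1 + z * se0, b1 + bint + z * se1)))
  out <- list(modifier = modifier, family = fit$family,
              subgroups = subgroups, beta1 = b1, beta_int = bint,
              se_int = se_int,
              p_interaction = 2 * pnorm(-abs(bint / se_int)),
              coefficients = cf, vcov = V)
  class(out) <- "wqs_interaction"
  out
}

#' @export
print.wqs_interaction <- function(x, ...) {
  lab <- if (x$family == "binomial") "aOR" else "aHR"
  cat("Effect-measure modification by '", x$modifier, "'\n", sep = "")
  for (i in 1:2)
    cat(sprintf("  %s = %d: %s %.4f (95%% CI %.4f-%.4f)\n",
                x$modifier, x$subgroups$level[i], lab,
                x$subgroups$estimate[i], x$subgroups$lower[i],
                x$subgroups$upper[i]))
  cat(sprintf("  P for interaction (Wald): %.4g\n", x$p_interaction))
  invisible(x)
}
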