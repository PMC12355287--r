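#' Expand follow-up into person-month records
#'
#' Converts one row per subject (follow-up length in months plus an
#' event flag) into one row per person-month: a subject followed for T
#' months contributes rows t = 1, ..., T, with the event indicator
#' equal to 1 only in the final row and only if the event occurred.  A
#' subject censored at 24 months therefore contributes exactly 24
#' event-free rows and leaves the risk set afterwards.  Follow-up is
#' administratively truncated at \code{max_months}; an event recorded
#' beyond the truncation point becomes a censoring at
#' \code{max_months} (logged).
#'
#' @param followup data frame with columns \code{id}, \code{months}
#'   (integer follow-up length, >= 1) and \code{event} (0/1).  Any
#'   additional columns (mixture index, covariates) are carried onto
#'   every person-month row unchanged (time-fixed).
#' @param max_months administrative censoring horizon (60 = five
#'   years).
#' @return data frame with columns \code{id}, \code{t}, \code{Y} plus
#'   the carried covariates, classed \code{person_period}.
#' @examples
#' expand_person_periods(data.frame(id = 1, months = 3, event = 1))
#' @export
expand_person_periods <- function(followup, max_months = 60L) {
  stopifnot(is.data.frame(followup),
            all(c("id", "months", "event") %in% names(followup)))
  months <- as.integer(followup$months)
  event <- as.integer(followup$event)
  if (any(is.na(months)) || any(months < 1L))
    stop("follow-up months must be integers >= 1")
  if (!all(event %in% c(0L, 1L))) stop("event flag must be 0/1")
  over <- months > max_months
  if (any(over & event == 1L))
    message(sum(over & event == 1L),
            " event(s) beyond ", max_months,
            " months administratively censored")
  event[over] <- 0L
  months <- pmin(months, as.integer(max_months))
  n <- nrow(followup)
  idx <- rep.int(seq_len(n), months)
  t <- sequence(months)
  Y <- integer(length(t))
  last <- cumsum(months)
  Y[last] <- event
  keep <- setdiff(names(followup), c("months", "event"))
  out <- cbind(followup[idx, keep, drop = FALSE],
               t = t, Y = Y)
  rownames(out) <- NULL
  class(out) <- c("person_period", "data.frame")
  attr(out, "max_months") <- as.integer(max_months)
  out
}

#' Truncate a person-period table at a follow-up horizon
#'
#' Sensitivity-analysis helper: restricts the analysis to the first
#' \code{horizon} months after transplant.  Rows beyond the horizon are
#' dropped, so an event occurring after the horizon is implicitly
#' re-coded as a censoring at the horizon.
#'
#' @param ppt a \code{person_period} table.
#' @param horizon months of follow-up to retain (>= 1).
#' @return the truncated \code{person_period} table.
#' @export
truncate_followup <- function(ppt, horizon = 12L) {
  stopifnot(inherits(ppt, "person_period"), horizon >= 1L)
  out <- ppt[ppt$t <= horizon, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("person_period", "data.frame")
  attr(out, "max_months") <- min(attr(ppt, "max_months"),
                                 as.integer(horizon))
  out
}

#' Natural cubic spline basis for the time variable
#'
#' Builds the flexible-baseline-hazard basis used by the pooled
#' logistic model: a natural cubic spline (linear beyond its boundary
#' knots) with \code{df} columns, interior knots at equally spaced
#' quantiles of the observed event times and boundary knots at the
#' range of observed person-months.
#'
#' @param t integer vector of person-months at which to evaluate.
#' @param df basis dimension (number of columns), >= 1.
#' @param event_times times used to place the interior knots; defaults
#'   to \code{t} itself.
#' @param knots,boundary optional explicit interior/boundary knots
#'   (used to re-evaluate a previously constructed basis on new data).
#' @return numeric matrix with \code{df} columns and attributes
#'   \code{"knots"} and \code{"boundary"}.
#' @export
natural_spline_basis <- function(t, df = 4L, event_times = t,
                                 knots = NULL, boundary = NULL) {
  if (df < 1L) stop("df must be >= 1")
  if (is.null(boundary)) boundary <- range(t)
  if (is.null(knots)) {
    if (df > 1L) {
      probs <- seq_len(df - 1L) / df
      knots <- unname(quantile(event_times, probs = probs, type = 7))
      if (length(unique(c(boundary[1], knots, boundary[2]))) < df + 1L)
        stop("too few distinct event times to place ", df - 1L,
             " interior knots; reduce df or pool months")
    } else knots <- numeric(0)
  }
  B <- splines::ns(t, knots = knots, Boundary.knots = boundary)
  B <- unclass(B)[, , drop = FALSE]
  colnames(B) <- paste0("ns", seq_len(ncol(B)))
  attr(B, "knots") <- knots
  attr(B, "boundary") <- boundary
  B
}

#' Pooled logistic regression with a spline baseline hazard
#'
#' Fits the discrete-time hazard model
#' \deqn{logit P(Y_t = 1 \mid Y_{t-1} = 0) =
#'   \beta_0 + \beta_1 wqs + \gamma' Z + \beta_t' S(t)}
#' by logistic regression over all person-month rows, where S(t) is a
#' natural cubic spline in months since transplant.  When monthly event
#' risks are small this approximates a Cox proportional-hazards model,
#' and \eqn{exp(\beta_1)} is reported as an adjusted hazard ratio (aHR)
#' per one-decile increase in the mixture index.  The model is
#' parameterized on the event indicator, so aHR > 1 means increased
#' hazard.
#'
#' @param ppt a \code{person_period} table containing \code{Y},
#'   \code{t}, the exposure column and covariates.
#' @param exposure name of the exposure column (the mixture index).
#' @param covariates character vector of covariate column names.
#' @param spline_df degrees of freedom for the baseline-hazard spline.
#' @return object of class \code{pooled_logistic}: coefficient table,
#'   \code{beta1}, Wald \code{ci95}, \code{aHR} with CI,
#'   \code{n_periods}, \code{n_events}, and the spline knots.
#' @export
fit_pooled_logistic <- function(ppt, exposure = "wqs",
                                covariates = character(0),
                                spline_df = 4L) {
  stopifnot(is.data.frame(ppt), all(c("Y", "t") %in% names(ppt)),
            exposure %in% names(ppt),
            all(covariates %in% names(ppt)))
  n_events <- sum(ppt$Y)
  if (n_events < 1L) stop("no events in the person-period table")
  S <- natural_spline_basis(ppt$t, df = spline_df,
                            event_times = ppt$t[ppt$Y == 1L])
  X <- cbind(ppt[, c(exposure, covariates), drop = FALSE],
             as.data.frame(S))
  dat <- cbind(Y = ppt$Y, X)
  fit <- glm(Y ~ ., data = dat, family = binomial())
  if (!fit$converged)
    warning("pooled logistic fit did not converge; ",
            "possible separation in the person-period data")
  cf <- coef(fit)
  V <- vcov(fit)
  b1 <- unname(cf[exposure])
  se1 <- sqrt(V[exposure, exposure])
  z <- qnorm(0.975)
  ci <- b1 + c(-1, 1) * z * se1
  out <- list(coefficients = cf, vcov = V, beta1 = b1, se = se1,
              ci95 = ci, aHR = exp(b1), aHR_ci95 = exp(ci),
              n_periods = nrow(ppt), n_events = n_events,
              spline_df = spline_df, knots = attr(S, "knots"),
              boundary = attr(S, "boundary"),
              exposure = exposure, covariates = covariates,
              glm_converged = fit$converged)
  class(out) <- "pooled_logistic"
  out
}

#' @export
print.pooled_logistic <- function(x, ...) {
  cat("Pooled logistic discrete-time hazard model\n")
  cat(sprintf("  person-months: %d   events: %d   spline df: %d\n",
              x$n_periods, x$n_events, x$spline_df))
  cat(sprintf("  aHR per 1-decile increase in %s: %.4f (95%% CI %.4f-%.4f)\n",
              x$exposure, x$aHR, x$aHR_ci95[1], x$aHR_ci95[2]))
  invisible(x)
}
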