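# Lognormal marginal parameters for the 15 constituents: medians and
# interquartile ranges typical of zip-code-level annual means in the
# contiguous US (units as in WQS_CONSTITUENT_UNITS).  meanlog is the log
# median; sdlog is the log-IQR divided by 2*qnorm(0.75).
CONSTITUENT_MARGINALS <- data.frame(
  constituent = c("Br", "Ca", "Cu", "EC", "Fe", "K", "NH4", "Ni",
                  "NO3", "OC", "Pb", "Si", "SO4", "V", "Zn"),
  median = c(3.0, 40.1, 2.7, 0.6, 65.8, 58.5, 0.9, 0.6, 1.1, 1.8,
             1.9, 85.4, 2.1, 0.8, 8.1),
  q1 = c(2.6, 30.1, 1.7, 0.4, 50.7, 51.9, 0.6, 0.4, 0.7, 1.5, 1.3,
         61.7, 1.5, 0.4, 5.9),
  q3 = c(3.4, 58.2, 4.0, 0.7, 84.7, 67.2, 1.3, 0.9, 1.7, 2.3, 2.9,
         129.4, 3.1, 1.5, 10.9))

#' Exchangeable-plus-block correlation matrix for constituent fields
#'
#' Builds the default dependence structure of the synthetic exposure
#' panel: exchangeable correlation \code{rho} between all constituents,
#' with a tighter block among the secondary-aerosol species (sulfate,
#' nitrate, ammonium, organic carbon), which co-vary strongly in
#' ambient data because they share precursors and chemistry.
#'
#' @param constituents constituent names.
#' @param rho baseline pairwise correlation.
#' @param block names in the high-correlation block.
#' @param rho_block within-block correlation.
#' @return a positive-definite correlation matrix.
#' @export
constituent_correlation <- function(constituents = WQS_CONSTITUENTS,
                                    rho = 0.5,
                                    block = c("SO4", "NO3", "NH4", "OC"),
                                    rho_block = 0.85) {
  J <- length(constituents)
  C <- matrix(rho, J, J, dimnames = list(constituents, constituents))
  inb <- intersect(block, constituents)
  C[inb, inb] <- rho_block
  diag(C) <- 1
  C
}

#' Configuration for the synthetic-cohort generator
#'
#' Collects every parameter of the generating model: the cohort and
#' panel sizes, the Gaussian-copula correlation of the lognormal
#' constituent fields, the true simplex weight vector \code{w_true},
#' the true per-decile log effects for each outcome, covariate effects,
#' the monthly baseline hazard schedule, and the censoring rate.
#' Defaults give a DGF-like binary outcome (baseline prevalence 18.6\%
#' at the mean index) with a strong three-constituent signal
#' (Ni 0.5, Pb 0.3, Zn 0.2; per-decile OR 1.2), and survival outcomes
#' with modest per-decile hazard ratios (1.047 graft failure, 1.039
#' death) on a gently declining monthly baseline hazard.
#'
#' @param n_recipients cohort size.
#' @param n_zips number of residential zip codes.
#' @param tx_year transplant calendar year (panel covers this year and
#'   the one before).
#' @param constituents constituent names (J components).
#' @param corr J x J correlation matrix for the Gaussian copula.
#' @param w_true named true weight vector on the simplex.
#' @param beta1_dgf,beta1_rejection true per-decile log odds ratios for
#'   the two binary outcomes.
#' @param beta1_graft,beta1_death true per-decile log hazard ratios for
#'   the two survival outcomes.
#' @param prevalence_dgf,prevalence_rejection baseline outcome
#'   probabilities at the mean mixture index.
#' @param gamma named covariate effects (log scale), applied to
#'   centered covariates in every outcome model.
#' @param hazard monthly baseline discrete hazard schedule, length
#'   \code{max_months}, each in (0, 1).
#' @param censor_hazard monthly probability of loss to follow-up.
#' @param max_months administrative censoring horizon.
#' @param confounding strength of the association between the
#'   area-deprivation covariate and zip-level log sulfate (0 = none).
#' @param q,B,train_fraction analysis defaults carried in the config.
#' @param seed master seed; all generator streams derive from it.
#' @return a classed list (\code{wqs_sim_config}).
#' @export
sim_config <- function(n_recipients = 2000L, n_zips = 200L,
                       tx_year = 2006L,
                       constituents = WQS_CONSTITUENTS,
                       corr = constituent_correlation(constituents),
                       w_true = NULL,
                       beta1_dgf = log(1.2),
                       beta1_rejection = log(1.2),
                       beta1_graft = log(1.047),
                       beta1_death = log(1.039),
                       prevalence_dgf = 0.186,
                       prevalence_rejection = 0.084,
                       gamma = c(age = 0.015, sex = -0.10,
                                 donor_deceased = 0.40, cit = 0.010,
                                 deprivation = 0.10),
                       hazard = 0.0012 + 0.0035 * exp(-(1:60) / 24),
                       censor_hazard = 0.003,
                       max_months = 60L,
                       confounding = 0,
                       q = 10L, B = 100L, train_fraction = 0.4,
                       seed = 1L) {
  if (is.null(w_true)) {
    # signal on trace elements outside the secondary-aerosol block:
    # weights inside an 0.85-correlated block are not individually
    # identifiable, which would defeat ground-truth recovery checks
    w_true <- setNames(numeric(length(constituents)), constituents)
    w_true[c("Ni", "Pb", "Zn")] <- c(0.5, 0.3, 0.2)
  }
  if (abs(sum(w_true) - 1) > 1e-8 || any(w_true < 0))
    stop("w_true must be non-negative and sum to 1")
  if (!isTRUE(all.equal(dim(corr), rep(length(constituents), 2L))))
    stop("corr must be J x J")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("corr is not positive definite; consider projecting to the ",
         "nearest correlation matrix (e.g. Matrix::nearPD)")
  if (any(hazard <= 0 | hazard >= 1))
    stop("hazard schedule must lie strictly inside (0, 1)")
  if (length(hazard) != max_months)
    stop("hazard schedule must have length max_months")
  cfg <- list(n_recipients = as.integer(n_recipients),
              n_zips = as.integer(n_zips), tx_year = as.integer(tx_year),
              constituents = constituents, corr = corr,
              w_true = w_true[constituents],
              beta1_dgf = beta1_dgf, beta1_rejection = beta1_rejection,
              beta1_graft = beta1_graft, beta1_death = beta1_death,
              prevalence_dgf = prevalence_dgf,
              prevalence_rejection = prevalence_rejection,
              gamma = gamma, hazard = hazard,
              censor_hazard = censor_hazard,
              max_months = as.integer(max_months),
              confounding = confounding,
              q = as.integer(q), B = as.integer(B),
              train_fraction = train_fraction, seed = as.integer(seed))
  class(cfg) <- "wqs_sim_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an annual constituent panel
#'
#' Draws zip-code-level annual mean concentrations for two consecutive
#' calendar years (the transplant year and the year before, as required
#' by the one-year moving average) from a Gaussian copula with the
#' configured correlation and lognormal marginals whose medians and
#' IQRs match typical US zip-code-level values.  Years are drawn
#' independently; all values are strictly positive.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional override of the config seed.
#' @return a \code{constituent_panel} with \code{2 * n_zips} rows.
#' @export
simulate_constituent_panel <- function(config, seed = config$seed) {
  cons <- config$constituents
  m <- CONSTITUENT_MARGINALS[match(cons, CONSTITUENT_MARGINALS$constituent), ]
  if (any(is.na(m$median)))
    stop("no marginal defaults for constituents: ",
         paste(cons[is.na(m$median)], collapse = ", "))
  meanlog <- log(m$median)
  sdlog <- (log(m$q3) - log(m$q1)) / (2 * qnorm(0.75))
  L <- chol(config$corr)
  nz <- config$n_zips
  zips <- sprintf("%05d", seq_len(nz))
  years <- c(config$tx_year - 1L, config$tx_year)
  with_seed(derive_seed(seed, "panel"), {
    Zn <- matrix(rnorm(2L * nz * length(cons)), 2L * nz) %*% L
    U <- pnorm(Zn)
    X <- sapply(seq_along(cons),
                function(j) qlnorm(U[, j], meanlog[j], sdlog[j]))
    colnames(X) <- cons
    as_constituent_panel(data.frame(zip = rep(zips, 2L),
                                    year = rep(years, each = nz),
                                    X, check.names = FALSE))
  })
}

#' Simulate recipient covariates and zip assignment
#'
#' Recipients receive a residential zip code by a skewed multinomial
#' (emulating urban clustering), a uniform transplant month, and the
#' covariate set: age (years), female sex, deceased-donor indicator,
#' cold ischemia time (hours), and an area-level deprivation score.
#' When \code{confounding > 0}, the deprivation score is shifted by the
#' zip's standardized log sulfate level, inducing exposure-covariate
#' confounding of the configured strength.
#'
#' @inheritParams simulate_constituent_panel
#' @param panel the simulated panel (needed only when
#'   \code{confounding > 0}).
#' @return data frame with one row per recipient.
#' @export
simulate_recipients <- function(config, panel = NULL,
                                seed = config$seed) {
  n <- config$n_recipients
  nz <- config$n_zips
  with_seed(derive_seed(seed, "cohort"), {
    sizes <- rexp(nz)^1.5
    zips <- sprintf("%05d", sample.int(nz, n, replace = TRUE,
                                       prob = sizes / sum(sizes)))
    dep <- rnorm(n)
    if (config$confounding > 0) {
      if (is.null(panel)) stop("panel required when confounding > 0")
      so4 <- panel[panel$year == config$tx_year, c("zip", "SO4")]
      lv <- setNames(as.numeric(scale(log(so4$SO4))), so4$zip)
      dep <- dep + config$confounding * lv[zips]
    }
    data.frame(id = seq_len(n), zip = zips,
               tx_year = config$tx_year,
               tx_month = sample.int(12L, n, replace = TRUE),
               age = rnorm(n, 51.6, 13.5),
               sex = rbinom(n, 1L, 0.39),
               donor_deceased = rbinom(n, 1L, 0.70),
               cit = rgamma(n, shape = 4, scale = 4.5),
               deprivation = as.numeric(dep))
  })
}

# Centered covariate linear predictor gamma' Z for the generating
# models; centering keeps the configured baseline rates interpretable.
covariate_lp <- function(recipients, gamma) {
  Z <- cbind(age = recipients$age - 51.6,
             sex = recipients$sex - 0.39,
             donor_deceased = recipients$donor_deceased - 0.70,
             cit = recipients$cit - 18,
             deprivation = recipients$deprivation)
  drop(Z[, names(gamma), drop = FALSE] %*% gamma)
}

#' Simulate a binary outcome from the weighted decile index
#'
#' Draws \eqn{Y \sim Bernoulli(expit(\beta_0 + \beta_1 \sum_i w^*_i d_i
#' + \gamma' Z))}, where the deciles are computed from the linked
#' moving-average exposures of the full cohort and \eqn{\beta_0} is
#' chosen so the outcome probability equals \code{prevalence} at the
#' cohort-mean index and covariates.
#'
#' @param deciles integer matrix of decile scores (rows aligned with
#'   \code{recipients}).
#' @param recipients recipient table from
#'   \code{\link{simulate_recipients}}.
#' @param config a \code{\link{sim_config}}.
#' @param beta1 per-decile log odds ratio.
#' @param prevalence baseline probability at the mean index.
#' @param seed RNG seed for the outcome stream.
#' @return list with \code{y} (0/1 vector), \code{beta0}, and the true
#'   index values.
#' @export
simulate_binary_outcome <- function(deciles, recipients, config,
                                    beta1 = config$beta1_dgf,
                                    prevalence = config$prevalence_dgf,
                                    seed = config$seed) {
  idx <- mixture_index(deciles, config$w_true)
  lp_z <- covariate_lp(recipients, config$gamma)
  beta0 <- qlogis(prevalence) - beta1 * mean(idx)
  p <- plogis(beta0 + beta1 * idx + lp_z)
  y <- with_seed(seed, rbinom(length(p), 1L, p))
  list(y = y, beta0 = beta0, index = idx)
}

#' Simulate discrete-time survival from the monthly hazard model
#'
#' Month by month, subjects still at risk have an event with
#' probability \eqn{expit(logit(h_t) + \beta_1 wqs + \gamma' Z)} and
#' are otherwise lost to follow-up with probability
#' \code{censor_hazard} (an event in the same month takes precedence).
#' Survivors are administratively censored at \code{max_months}.
#'
#' @inheritParams simulate_binary_outcome
#' @param beta1 per-decile log hazard ratio.
#' @param hazard monthly baseline hazard schedule; defaults to the
#'   config schedule.
#' @return list with integer \code{months}, 0/1 \code{event}, and the
#'   true index values.
#' @export
simulate_survival_outcome <- function(deciles, recipients, config,
                                      beta1 = config$beta1_graft,
                                      hazard = config$hazard,
                                      seed = config$seed) {
  if (any(hazard < 0 | hazard >= 1))
    stop("hazard schedule must lie in [0, 1)")
  idx <- mixture_index(deciles, config$w_true)
  lp <- beta1 * idx + covariate_lp(recipients, config$gamma)
  n <- length(idx)
  mm <- config$max_months
  months <- rep.int(mm, n)
  event <- integer(n)
  with_seed(seed, {
    at_risk <- rep(TRUE, n)
    for (t in seq_len(mm)) {
      if (!any(at_risk)) break
      i <- which(at_risk)
      pe <- if (hazard[t] > 0) plogis(qlogis(hazard[t]) + lp[i])
            else numeric(length(i))
      ev <- runif(length(i)) < pe
      cs <- !ev & (runif(length(i)) < config$censor_hazard)
      done <- ev | cs
      months[i[done]] <- t
      event[i[ev]] <- 1L
      at_risk[i[done]] <- FALSE
    }
  })
  list(months = as.integer(months), event = event, index = idx)
}

#' Simulate a complete synthetic transplant cohort
#'
#' Runs the whole generating model: constituent panel, recipients with
#' covariates, moving-average exposure linkage, decile transformation,
#' two binary outcomes (DGF-like and rejection-like), and two
#' discrete-time survival outcomes (death, and graft failure censored
#' at death).  The ground-truth record carries every parameter needed
#' to score recovery.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{wqs_sim}: \code{panel}, \code{cohort}
#'   (recipients with outcome columns), \code{truth}, \code{config}.
#' @export
simulate_wqs_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "wqs_sim_config"))
  panel <- simulate_constituent_panel(config)
  rec <- simulate_recipients(config, panel = panel)
  expo <- link_exposures(panel, rec, policy = "strict")
  dec <- quantile_transform(expo, q = config$q)
  D <- as.matrix(dec[, config$constituents, drop = FALSE])

  sd_base <- config$seed
  dgf <- simulate_binary_outcome(D, rec, config,
                                 beta1 = config$beta1_dgf,
                                 prevalence = config$prevalence_dgf,
                                 seed = derive_seed(sd_base, "outcome", 1L))
  rej <- simulate_binary_outcome(D, rec, config,
                                 beta1 = config$beta1_rejection,
                                 prevalence = config$prevalence_rejection,
                                 seed = derive_seed(sd_base, "outcome", 2L))
  death <- simulate_survival_outcome(D, rec, config,
                                     beta1 = config$beta1_death,
                                     seed = derive_seed(sd_base, "survival", 1L))
  graft <- simulate_survival_outcome(D, rec, config,
                                     beta1 = config$beta1_graft,
                                     seed = derive_seed(sd_base, "survival", 2L))
  # death-censored graft failure: dying event-free censors the graft
  # process at the death month
  g_months <- pmin(graft$months, death$months)
  g_event <- as.integer(graft$event == 1L & graft$months <= death$months)

  cohort <- cbind(rec,
                  dgf = dgf$y, rejection = rej$y,
                  months_death = death$months, event_death = death$event,
                  months_graft = g_months, event_graft = g_event)
  truth <- list(w_true = config$w_true,
                beta1 = c(dgf = config$beta1_dgf,
                          rejection = config$beta1_rejection,
                          death = config$beta1_death,
                          graft = config$beta1_graft),
                beta0_dgf = dgf$beta0, beta0_rejection = rej$beta0,
                gamma = config$gamma, hazard = config$hazard,
                censor_hazard = config$censor_hazard,
                index = dgf$index, seed = config$seed)
  out <- list(panel = panel, cohort = cohort, exposures = expo,
              truth = truth, config = config)
  class(out) <- "wqs_sim"
  out
}

#' Merge simulated exposures onto the cohort table
#'
#' Convenience accessor producing the one-row-per-recipient analysis
#' table that \code{\link{wqs}} expects: outcomes, covariates, and one
#' concentration column per constituent.
#'
#' @param sim a \code{wqs_sim} object.
#' @return data frame.
#' @export
wqs_analysis_table <- function(sim) {
  stopifnot(inherits(sim, "wqs_sim"))
  merge(sim$cohort, sim$exposures, by = "id", sort = TRUE)
}
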