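test_that("simulated panels have the configured copula correlation", {
  cons <- c("Ni", "Pb", "SO4", "NO3")
  m <- diag(4); dimnames(m) <- list(cons, cons)
  m["SO4", "NO3"] <- m["NO3", "SO4"] <- 0.7
  cfg <- sim_config(n_zips = 4000L, constituents = cons, corr = m,
                    w_true = setNames(c(1, 0, 0, 0), cons), seed = 2L)
  panel <- simulate_constituent_panel(cfg)
  expect_true(all(as.matrix(panel[, cons]) > 0))
  lc <- cor(log(as.matrix(panel[, cons])))
  expect_lt(max(abs(lc[lower.tri(lc)] - m[lower.tri(m)])), 0.05)
  # non-PD correlation is rejected up front
  bad <- m; bad["Ni", "Pb"] <- bad["Pb", "Ni"] <- 1.2
  expect_error(sim_config(constituents = cons, corr = bad,
                          w_true = setNames(c(1, 0, 0, 0), cons)),
               "positive definite")
})

test_that("panel marginals sit at their configured medians", {
  cfg <- sim_config(n_zips = 3000L, seed = 4L)
  panel <- simulate_constituent_panel(cfg)
  med <- apply(as.matrix(panel[, cfg$constituents]), 2, median)
  ref <- wqsmix:::CONSTITUENT_MARGINALS
  expect_lt(max(abs(log(med) -
                      log(ref$median[match(names(med), ref$constituent)]))),
            0.1)
})

test_that("binary outcomes hit the configured baseline prevalence", {
  cfg <- sim_config(n_recipients = 10000L, n_zips = 400L, seed = 6L)
  panel <- simulate_constituent_panel(cfg)
  rec <- simulate_recipients(cfg, panel)
  expo <- link_exposures(panel, rec, policy = "strict")
  D <- as.matrix(quantile_transform(expo)[, cfg$constituents])
  # null mixture effect and null covariates: pure binomial check
  cfg0 <- cfg; cfg0$gamma <- cfg$gamma * 0
  out <- simulate_binary_outcome(D, rec, cfg0, beta1 = 0,
                                 prevalence = 0.186, seed = 11L)
  se <- sqrt(0.186 * (1 - 0.186) / 10000)
  expect_lt(abs(mean(out$y) - 0.186), 3 * se)
  # saturating intercept: beta1 large negative implies no events
  out0 <- simulate_binary_outcome(D, rec, cfg0, beta1 = 0,
                                  prevalence = 1e-12, seed = 11L)
  expect_identical(sum(out0$y), 0L)
  # a logistic fit on the true index recovers beta1
  out1 <- simulate_binary_outcome(D, rec, cfg0, beta1 = log(1.2),
                                  prevalence = 0.186, seed = 12L)
  g <- glm(out1$y ~ out1$index, family = binomial())
  expect_lt(abs(coef(g)[2] - log(1.2)), 3 * summary(g)$coefficients[2, 2])
})

test_that("discrete-time survival follows the closed-form survivor curve", {
  cfg <- sim_config(n_recipients = 8000L, n_zips = 300L,
                    hazard = rep(0.01, 60), censor_hazard = 0,
                    seed = 14L)
  panel <- simulate_constituent_panel(cfg)
  rec <- simulate_recipients(cfg, panel)
  expo <- link_exposures(panel, rec, policy = "strict")
  D <- as.matrix(quantile_transform(expo)[, cfg$constituents])
  cfg0 <- cfg; cfg0$gamma <- cfg$gamma * 0
  sv <- simulate_survival_outcome(D, rec, cfg0, beta1 = 0, seed = 15L)
  # with beta1 = 0 and constant hazard h, P(T <= t) = 1 - (1-h)^t
  for (t in c(6L, 24L, 60L)) {
    p_t <- 1 - (1 - 0.01)^t
    obs <- mean(sv$months <= t & sv$event == 1L)
    expect_lt(abs(obs - p_t), 3 * sqrt(p_t * (1 - p_t) / 8000))
  }
  # zero hazard: everyone administratively censored
  sv0 <- simulate_survival_outcome(D, rec, cfg0, beta1 = 0,
                                   hazard = rep(0, 60), seed = 16L)
  expect_identical(sum(sv0$event), 0L)
  expect_true(all(sv0$months == 60L))
  expect_error(simulate_survival_outcome(D, rec, cfg0,
                                         hazard = rep(1.5, 60)),
               "hazard")
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- sim_config(n_recipients = 300L, seed = 21L)
  s1 <- simulate_wqs_cohort(cfg)
  s2 <- simulate_wqs_cohort(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- simulate_wqs_cohort(sim_config(n_recipients = 300L, seed = 22L))
  expect_false(identical(s1$cohort$dgf, s3$cohort$dgf))
})

test_that("the ground-truth record carries every generating parameter", {
  sim <- simulate_wqs_cohort(sim_config(n_recipients = 200L, seed = 23L))
  tr <- sim$truth
  expect_true(all(c("w_true", "beta1", "beta0_dgf", "gamma", "hazard",
                    "censor_hazard", "seed") %in% names(tr)))
  expect_equal(sum(tr$w_true), 1)
  expect_identical(names(tr$beta1), c("dgf", "rejection", "death", "graft"))
  # follow-up respects administrative censoring
  expect_true(all(sim$cohort$months_death >= 1L &
                    sim$cohort$months_death <= 60L))
  # confounding knob links deprivation to sulfate when requested
  cfgc <- sim_config(n_recipients = 4000L, confounding = 0.8, seed = 24L)
  pc <- simulate_constituent_panel(cfgc)
  rc <- simulate_recipients(cfgc, pc)
  so4 <- setNames(log(pc$SO4[pc$year == cfgc$tx_year]),
                  pc$zip[pc$year == cfgc$tx_year])
  expect_gt(cor(rc$deprivation, so4[rc$zip]), 0.2)
})
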