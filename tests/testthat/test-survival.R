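test_that("person-month expansion reproduces follow-up exactly", {
  # censored at 24 months: 24 rows, all event-free
  pp <- expand_person_periods(data.frame(id = 1L, months = 24L, event = 0L))
  expect_identical(nrow(pp), 24L)
  expect_true(all(pp$Y == 0L))
  expect_identical(pp$t, 1:24)

  # event in the first month: a single row with Y = 1
  pp1 <- expand_person_periods(data.frame(id = 1L, months = 1L, event = 1L))
  expect_identical(nrow(pp1), 1L)
  expect_identical(pp1$Y, 1L)

  # 5 + 12 + 60 = 77 rows, event only at the final row of subject 1
  fu <- data.frame(id = 1:3, months = c(5L, 12L, 60L), event = c(1L, 0L, 0L))
  pp3 <- expand_person_periods(fu)
  expect_identical(nrow(pp3), 77L)
  expect_identical(sum(pp3$Y), 1L)
  expect_identical(pp3$t[pp3$Y == 1L], 5L)

  expect_error(expand_person_periods(data.frame(id = 1, months = 0, event = 0)),
               ">= 1")
})

test_that("expansion conserves rows and the risk set shrinks over time", {
  set.seed(12)
  fu <- data.frame(id = 1:200,
                   months = sample(1:80, 200, replace = TRUE),
                   event = rbinom(200, 1, 0.3),
                   wqs = runif(200, 0, 9))
  expect_message(pp <- expand_person_periods(fu, max_months = 60L),
                 "administratively censored")
  expect_identical(nrow(pp), sum(pmin(fu$months, 60L)))
  # an event flag beyond the horizon is dropped with the truncation
  expect_true(all(pp$Y[pp$id %in% fu$id[fu$months > 60 & fu$event == 1]] == 0L))
  # risk-set monotonicity
  at_risk <- tabulate(pp$t, nbins = 60L)
  expect_true(all(diff(at_risk) <= 0))
  # covariates are carried unchanged onto every row
  expect_equal(pp$wqs[pp$id == 7L], rep(fu$wqs[7], min(fu$months[7], 60L)))
  # at most one event per subject, only at the last row
  last <- tapply(seq_len(nrow(pp)), pp$id, max)
  expect_true(all(pp$Y[-last] == 0L))
})

test_that("follow-up truncation recodes late events as censorings", {
  fu <- data.frame(id = 1:3, months = c(24L, 10L, 15L), event = c(0L, 1L, 1L))
  pp <- expand_person_periods(fu)
  tr <- truncate_followup(pp, horizon = 12L)
  expect_identical(nrow(tr[tr$id == 1L, ]), 12L)
  # event at month 10 is untouched
  expect_identical(tr[tr$id == 2L, ], pp[pp$id == 2L, ], ignore_attr = TRUE)
  # event at month 15 becomes 12 event-free rows
  expect_identical(nrow(tr[tr$id == 3L, ]), 12L)
  expect_true(all(tr$Y[tr$id == 3L] == 0L))
})

test_that("natural spline basis is deterministic and linear in the tails", {
  t <- 1:60
  B <- natural_spline_basis(t, df = 4L)
  expect_identical(ncol(B), 4L)
  expect_identical(B, natural_spline_basis(t, df = 4L))
  # second differences vanish on integer grids outside the boundary knots
  tt <- seq(61, 120)
  Bout <- natural_spline_basis(tt, df = 4L, knots = attr(B, "knots"),
                               boundary = attr(B, "boundary"))
  d2 <- apply(Bout, 2, function(col) diff(col, differences = 2))
  expect_lt(max(abs(d2)), 1e-9)
  expect_error(natural_spline_basis(c(1, 1, 1), df = 4L), "distinct")
})

test_that("spline basis spans the truncated-power natural spline space", {
  t <- 1:60
  B <- natural_spline_basis(t, df = 4L)
  knots_all <- c(attr(B, "boundary")[1], attr(B, "knots"),
                 attr(B, "boundary")[2])
  R <- tp_natural_spline(t, knots_all)
  # each basis lies in the span of the other (plus intercept)
  res1 <- lm.fit(cbind(1, R), B)$residuals
  res2 <- lm.fit(cbind(1, B), R)$residuals
  expect_lt(max(abs(res1)), 1e-8)
  expect_lt(max(abs(res2)), 1e-8)
})

test_that("pooled logistic recovers a known discrete-time hazard ratio", {
  cfg <- sim_config(n_recipients = 2500L,
                    hazard = rep(0.01, 60), censor_hazard = 0.002,
                    seed = 5L)
  panel <- simulate_constituent_panel(cfg)
  rec <- simulate_recipients(cfg, panel)
  expo <- link_exposures(panel, rec, policy = "strict")
  D <- as.matrix(quantile_transform(expo)[, cfg$constituents])
  sv <- simulate_survival_outcome(D, rec, cfg, beta1 = log(1.10), seed = 77L)
  fu <- data.frame(id = rec$id, months = sv$months, event = sv$event,
                   wqs = sv$index, age = rec$age, sex = rec$sex)
  pp <- expand_person_periods(fu)
  fit <- fit_pooled_logistic(pp, covariates = c("age", "sex"))
  expect_identical(fit$n_events, sum(sv$event))
  expect_true(fit$ci95[1] <= log(1.10) && log(1.10) <= fit$ci95[2])

  # independent continuous-time check: Cox partial likelihood on the
  # same data gives nearly the same log hazard ratio
  cx <- survival::coxph(survival::Surv(months, event) ~ wqs + age + sex,
                        data = fu)
  expect_lt(abs(coef(cx)["wqs"] - fit$beta1), 2 * fit$se)

  # permuting the exposure across subjects destroys the association
  set.seed(8)
  fu_perm <- fu
  fu_perm$wqs <- sample(fu$wqs)
  pperm <- expand_person_periods(fu_perm)
  fperm <- fit_pooled_logistic(pperm, covariates = c("age", "sex"))
  expect_true(fperm$ci95[1] <= 0 && 0 <= fperm$ci95[2])

  # raising the horizon without new events leaves the event count fixed
  fit12 <- fit_pooled_logistic(truncate_followup(pp, 12L),
                               covariates = c("age", "sex"))
  expect_lte(fit12$n_events, fit$n_events)
  expect_error(fit_pooled_logistic(pp[pp$Y == 0L, ][1:100, ]), "no events")
})

test_that("dying event-free censors the graft-failure process", {
  cfg <- sim_config(n_recipients = 400L, seed = 9L)
  sim <- simulate_wqs_cohort(cfg)
  co <- sim$cohort
  # graft failure can never be recorded after death
  expect_true(all(co$months_graft <= co$months_death))
  died_first <- co$event_death == 1L & co$months_death < co$months_graft
  expect_true(all(co$event_graft[died_first] == 0L))
})
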