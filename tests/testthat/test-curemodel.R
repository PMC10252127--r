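test_that("E-step posterior weights follow the mixture algebra", {
  S0 <- step_surv(c(1, 2), c(0.5, 0.25), hazard = c(log(2), log(2)),
                  tail = "zero")
  z <- cbind(1, c(0, 0, 0))
  x <- matrix(numeric(0), 3, 0)
  # pi = 0.8, censored at t = 2 where Su = 0.25:
  # w = 0.8 * 0.25 / (0.2 + 0.8 * 0.25) = 0.5
  w <- estep_weights(b = c(qlogis(0.8), 0), beta = numeric(0), S0 = S0,
                     time = c(2, 0.5, 1.5), event = c(0, 0, 1), z = z, x = x)
  expect_equal(w[[1]], 0.5)
  # censored before the first event: Su = 1 so w = pi
  expect_equal(w[[2]], 0.8)
  expect_equal(w[[3]], 1)                       # events always 1
  # pi = 1 for all: ordinary Cox data
  w1 <- estep_weights(c(30, 0), numeric(0), S0, c(2, 0.5, 1.5),
                      c(0, 0, 1), z, x)
  expect_equal(as.numeric(w1), c(1, 1, 1), tolerance = 1e-10)
  # guard: pi = 1 and Su = 0 (censored after last event) -> w = 0, noted
  wg <- estep_weights(c(30, 0), numeric(0), S0, time = 3, event = 0,
                      z = cbind(1, 0), x = matrix(numeric(0), 1, 0))
  expect_equal(as.numeric(wg), 0)
  expect_true(attr(wg, "guarded"))
})

test_that("incidence M-step solves the fractional-response likelihood", {
  # intercept-only with w = 0.5 everywhere: logit(0.5) = 0
  f <- mstep_incidence(cbind(rep(1, 20)), rep(0.5, 20))
  expect_equal(unname(f$coef), 0, tolerance = 1e-8)
  expect_lt(f$score_norm, 1e-8)
  # all w = 1: intercept runs to the cap and is flagged
  f1 <- suppressWarnings(mstep_incidence(cbind(rep(1, 20)), rep(1, 20)))
  expect_true("boundary" %in% f1$flags)
  expect_equal(unname(f1$coef), 20)
  # grid-search oracle for a 1-parameter fractional-response likelihood
  set.seed(9)
  w <- runif(40)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b) sum(w * b - log(1 + exp(b))), numeric(1))
  f2 <- mstep_incidence(cbind(rep(1, 40)), w)
  expect_lt(abs(unname(f2$coef) - grid[which.max(ll)]), 1e-4)
})

test_that("logit_fit agrees with glm on ordinary data", {
  set.seed(12)
  n <- 200
  z <- cbind(1, a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * z[, 2]))
  f <- logit_fit(z, y)
  g <- glm(y ~ z[, 2] + z[, 3], family = binomial)
  expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-6)
})

test_that("latency M-step reduces to ordinary Cox and obeys the zero tail", {
  set.seed(14)
  n <- 80
  x <- cbind(x = rnorm(n))
  time <- rexp(n); event <- rbinom(n, 1, 0.6)
  m <- mstep_latency(time, event, x, rep(1, n))
  f <- cox_fit(time, event, x)
  expect_equal(m$coef, f$coef, tolerance = 1e-10)
  expect_equal(m$baseline$surv, f$baseline$surv, tolerance = 1e-10)
  # zero-tail: baseline is exactly 0 beyond the last event time
  expect_equal(survival_at(m$baseline, max(time[event == 1]) + 1e-9), 0)
  # w = 0 for all censored: identical to the fit on the events-only multiset
  w0 <- ifelse(event == 1, 1, 0)
  m0 <- mstep_latency(time, event, x, w0)
  fe <- cox_fit(time[event == 1], event[event == 1],
                x[event == 1, , drop = FALSE])
  expect_equal(m0$coef, fe$coef, tolerance = 1e-10)
})

test_that("observed-data log-likelihood matches hand computation and is additive", {
  # single censored subject at t = 0 with empty baseline: log(1) = 0
  S0e <- step_surv(1, 0.5, hazard = log(2), tail = "zero")
  ll0 <- observed_loglik(b = 0, beta = numeric(0), S0 = S0e, time = 0,
                         event = 0, z = cbind(1), x = matrix(numeric(0), 1, 0))
  expect_equal(ll0, log(1 - plogis(0) + plogis(0) * 1))
  # single event: log pi + log dH + eta - H e^eta (discrete Breslow, H
  # includes the jump at t)
  b <- 0.3; dH <- log(2); H <- log(2)
  ll1 <- observed_loglik(b = b, beta = numeric(0), S0 = S0e, time = 1,
                         event = 1, z = cbind(1), x = matrix(numeric(0), 1, 0))
  expect_equal(ll1, log(plogis(b)) + log(dH) - H)
  # additivity: duplicating every subject doubles the log-likelihood
  set.seed(15)
  d <- tiny_sample(2)
  fit <- suppressWarnings(curemix_fit(d$time, d$event,
                                      cbind(rep(1, length(d$time))),
                                      matrix(numeric(0), length(d$time), 0)))
  ll <- observed_loglik(fit$b, fit$beta, fit$S0, d$time, d$event,
                        cbind(rep(1, length(d$time))),
                        matrix(numeric(0), length(d$time), 0))
  ll2 <- observed_loglik(fit$b, fit$beta, fit$S0, rep(d$time, 2),
                         rep(d$event, 2), cbind(rep(1, 2 * length(d$time))),
                         matrix(numeric(0), 2 * length(d$time), 0))
  expect_equal(ll2, 2 * ll, tolerance = 1e-10)
})

test_that("EM reduces to ordinary Cox when everyone is forced uncured", {
  set.seed(16)
  n <- 400
  x <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  time <- rexp(n, exp(0.5 * x[, 1]))
  cens <- runif(n, 0.5, 4)
  obs <- pmin(time, cens); ev <- as.numeric(time <= cens)
  fit <- suppressWarnings(curemix_fit(obs, ev, cbind(rep(1, n)), x,
                                      pi_fixed = 1))
  cox <- cox_fit(obs, ev, x)
  expect_equal(fit$beta, cox$coef, tolerance = 1e-6)
})

test_that("EM estimates a near-zero cure fraction when all are uncured", {
  spec <- cohort_spec(n = 5000, seed = 41,
                      incidence = list(formula = ~1,
                                       coef = c("(Intercept)" = 20)),
                      latency = list(formula = ~x1, coef = c(x1 = 0.4)),
                      censor_window = c(2, 9))
  coh <- simulate_cure_cohort(spec)
  fit <- suppressWarnings(
    curemix(cbind(time_years, event) ~ x1, cureform = ~1, data = coh$table))
  expect_lt(mean(predict_cure_probability(fit)), 0.02)
  unc <- cox_fit(coh$table$time_years, coh$table$event,
                 cbind(x1 = coh$table$x1))
  expect_equal(fit$beta[["x1"]], unc$coef[["x1"]], tolerance = 1e-2)
})

test_that("intercept-only cure fraction matches the KM plateau (NPMLE identity)", {
  q999 <- stats::qweibull(0.999, 1, 1.6 / log(2))
  spec <- cohort_spec(n = 10000, seed = 51,
                      incidence = list(formula = ~1,
                                       coef = c("(Intercept)" = qlogis(0.21))),
                      latency = list(formula = ~1, coef = numeric(0)),
                      baseline = list(shape = 1, scale = 1.6 / log(2)),
                      censor_window = c(q999, q999 + 4))
  coh <- simulate_cure_cohort(spec)
  fit <- suppressWarnings(curemix_fit(coh$table$time_years, coh$table$event,
                                      cbind(rep(1, 10000))))
  km <- km_estimate(coh$table$time_years, coh$table$event)
  plateau <- km$surv[length(km$surv)]
  expect_lt(abs(mean(predict_cure_probability(fit)) - plateau), 0.01)
})

test_that("predicted quantities follow the mixture identities", {
  set.seed(19)
  d <- tiny_sample(19, n = 150, cure = 0.4)
  df <- data.frame(time_years = d$time, event = d$event,
                   x1 = rnorm(150))
  fit <- suppressWarnings(curemix(cbind(time_years, event) ~ x1,
                                  cureform = ~ x1, data = df))
  # S = (1 - pi) + pi * Su pointwise, exactly
  z1 <- c(1, 0.7); x1 <- 0.7
  pi1 <- plogis(sum(z1 * fit$b))
  su <- uncured_survival(fit, x1)
  s <- predict_marginal_survival(fit, z1, x1)
  k <- length(su$surv)
  expect_equal(s$surv[seq_len(k)], (1 - pi1) + pi1 * su$surv,
               tolerance = 1e-12)
  expect_equal(s$surv[k + 1],
               (1 - pi1) + pi1 * survival_at(su, su$time[k] * 1.01),
               tolerance = 1e-12)
  # curve floor is the cure probability
  expect_equal(s$surv[length(s$surv)], 1 - pi1, tolerance = 1e-12)
  # b = 0 gives cure probability one half; means average per-patient values
  expect_equal(mean(c(0.6, 0.8, 1.0)), 0.8)
  fit0 <- fit; fit0$b[] <- 0
  expect_equal(unique(round(predict_cure_probability(fit0), 12)), 0.5)
  # ensemble curve equals the mean of individual curves at every knot
  mc <- marginal_mean_curve(fit)
  ind <- predict(fit, type = "survival")
  manual <- rowMeans(vapply(ind, function(ci) ci$surv,
                            numeric(length(mc$time))))
  expect_equal(mc$surv, manual, tolerance = 1e-12)
})

test_that("median uncured time matches the closed-form exponential median", {
  lam <- 1 / 1.6 * log(2)   # exponential with median 1.6
  spec <- cohort_spec(n = 10000, seed = 61,
                      incidence = list(formula = ~1,
                                       coef = c("(Intercept)" = qlogis(0.3))),
                      latency = list(formula = ~1, coef = numeric(0)),
                      baseline = list(shape = 1, scale = 1.6 / log(2)),
                      censor_window = c(1, 8.5))
  coh <- simulate_cure_cohort(spec)
  fit <- suppressWarnings(curemix_fit(coh$table$time_years, coh$table$event,
                                      cbind(rep(1, 10000))))
  med <- as.numeric(median_uncured_time(fit))
  expect_lt(abs(med - 1.6) / 1.6, 0.05)
  # pathological floor above one half: undefined sentinel
  bad <- step_surv(c(1, 2), c(0.9, 0.6))
  m <- median_uncured_time(bad)
  expect_true(is.na(m))
  expect_false(attr(m, "defined"))
})

test_that("parameter recovery within bootstrap uncertainty on one cohort", {
  spec <- cohort_spec(n = 5000, seed = 71)
  coh <- simulate_cure_cohort(spec)
  fit <- suppressWarnings(curemix(cbind(time_years, event) ~ x1,
                                  cureform = ~ x1, data = coh$table))
  boot <- suppressWarnings(cure_bootstrap(fit, B = 60, seed = 7))
  est <- c(fit$b, fit$beta)
  truth <- c(qlogis(0.21), 0.5, 0.5)
  expect_true(all(abs(est - truth) < 3 * boot$se))
})

test_that("bootstrap inference is reproducible and degenerate on constant cohorts", {
  set.seed(23)
  d <- tiny_sample(23, n = 120)
  df <- data.frame(time_years = d$time, event = d$event)
  fit <- suppressWarnings(curemix(cbind(time_years, event) ~ 1,
                                  cureform = ~ 1, data = df))
  b1 <- suppressWarnings(cure_bootstrap(fit, B = 50, seed = 99))
  b2 <- suppressWarnings(cure_bootstrap(fit, B = 50, seed = 99))
  expect_identical(b1$reps, b2$reps)
  # exchangeability: the fit depends on the rows as a multiset only, so
  # a resample drawing each subject exactly once reproduces the estimate
  perm <- sample(nrow(df))
  fp <- suppressWarnings(curemix(cbind(time_years, event) ~ 1,
                                 cureform = ~ 1, data = df[perm, ]))
  expect_equal(fp$b, fit$b, tolerance = 1e-9)
  expect_equal(fp$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("strata summaries aggregate correctly and flag empty strata", {
  spec <- cohort_spec(n = 3000, seed = 81,
                      incidence = list(formula = ~x1,
                                       coef = c("(Intercept)" = qlogis(0.25),
                                                x1 = 0.8)),
                      latency = list(formula = ~x1, coef = c(x1 = 0.3)))
  coh <- simulate_cure_cohort(spec)
  coh$table$x1_hi <- factor(coh$table$x1 > 0, c(FALSE, TRUE),
                            c("low", "high"))
  fit <- suppressWarnings(curemix(cbind(time_years, event) ~ x1,
                                  cureform = ~ x1, data = coh$table))
  s <- strata_summary(fit, strata = c("all", "x1_hi"))
  whole <- s[s$variable == "all", ]
  expect_equal(whole$cure_pct, 100 * mean(predict_cure_probability(fit)),
               tolerance = 1e-10)
  # positive incidence coefficient: high-x1 stratum less often cured
  hi <- s[s$level == "high", ]; lo <- s[s$level == "low", ]
  expect_lt(hi$cure_pct, lo$cure_pct)
  # empty stratum reported with n = 0 and no estimates
  coh$table$empty <- factor("a", levels = c("a", "b"))
  s2 <- strata_summary(fit, strata = "empty", newdata = coh$table)
  expect_equal(s2$n[s2$level == "b"], 0)
  expect_true(is.na(s2$cure_pct[s2$level == "b"]))
})

test_that("identifiability heuristic warns without a post-event plateau", {
  # last observation is an event: no censored subject beyond it
  df <- data.frame(time_years = c(1, 2, 3, 4), event = c(0, 1, 0, 1))
  expect_warning(curemix(cbind(time_years, event) ~ 1, cureform = ~ 1,
                         data = df, max_iter = 5),
                 "weakly identified")
})
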