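test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  # censoring at 2: risk set at 3 has a single subject
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$surv, c(2/3, 0))
  # duplicate-weight invariance
  km3 <- km_estimate(c(1, 2, 3), c(1, 0, 1), weights = rep(2, 3))
  expect_equal(km3$surv, km2$surv)
  expect_error(km_estimate(c(-1, 2), c(1, 0)), "nonnegative")
  # no events: degenerate curve is 1 everywhere
  km4 <- km_estimate(c(1, 2), c(0, 0))
  expect_equal(survival_at(km4, c(0, 5)), c(1, 1))
})

test_that("KM agrees with the survival package, including weights and Greenwood", {
  skip_if_not_installed("survival")
  set.seed(3)
  n <- 150
  time <- rexp(n); event <- rbinom(n, 1, 0.6); w <- runif(n, 0.3, 2.5)
  km <- km_estimate(time, event, weights = w)
  sf <- summary(survival::survfit(survival::Surv(time, event) ~ 1,
                                  weights = w),
                times = km$time)
  expect_equal(km$surv, sf$surv, tolerance = 1e-12)
  # Greenwood variance, unweighted case
  km_u <- km_estimate(time, event)
  sf_u <- summary(survival::survfit(survival::Surv(time, event) ~ 1),
                  times = km_u$time)
  expect_equal(sqrt(km_u$var), sf_u$std.err, tolerance = 1e-10)
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(8)
  time <- round(rexp(200), 2)
  km <- km_estimate(time, rep(1, 200))
  ecdf_vals <- 1 - stats::ecdf(time)(km$time)
  expect_equal(km$surv, ecdf_vals, tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("step-survival evaluation is right-continuous with correct tails", {
  s <- step_surv(c(1, 2), c(0.6, 0.2))
  expect_equal(survival_at(s, 0), 1)
  expect_equal(survival_at(s, 1), 0.6)    # post-jump value at a knot
  expect_equal(survival_at(s, 1.999), 0.6)
  expect_equal(survival_at(s, 10), 0.2)   # plateau tail
  sz <- step_surv(c(1, 2), c(0.6, 0.2), tail = "zero")
  expect_equal(survival_at(sz, 2), 0.2)
  expect_equal(survival_at(sz, 2.001), 0)
  expect_error(step_surv(c(2, 1), c(0.5, 0.4)), "increasing")
  expect_error(step_surv(c(1, 2), c(0.4, 0.5)), "nonincreasing")
})

test_that("median_from_curve flags curves that never cross one half", {
  expect_equal(as.numeric(median_from_curve(step_surv(2, 0.4))), 2)
  m <- median_from_curve(step_surv(c(1, 2), c(0.9, 0.6)))
  expect_true(is.na(m))
  expect_false(attr(m, "defined"))
})

test_that("log-rank matches brute-force O-E/V enumeration and survdiff", {
  # identical samples: statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  # brute force over the 4 event times of A=(1,2), B=(3,4), no censoring
  tA <- c(1, 2); tB <- c(3, 4)
  o <- e <- v <- 0
  for (t in c(1, 2, 3, 4)) {
    n1 <- sum(tA >= t); n2 <- sum(tB >= t); n <- n1 + n2
    o <- o + (t %in% tA)
    e <- e + n1 / n
    if (n > 1) v <- v + (n1 / n) * (n2 / n) * (n - 1) / (n - 1)
  }
  lr <- logrank_test(tA, c(1, 1), tB, c(1, 1))
  expect_equal(lr$statistic, (o - e)^2 / v)
  # degenerate: no events in one arm and every event in the other
  lr2 <- logrank_test(c(1, 2), c(1, 1), c(5, 6), c(0, 0))
  expect_true(is.finite(lr2$statistic))
  # rank invariance to common time rescaling
  set.seed(5)
  t1 <- rexp(30); e1 <- rbinom(30, 1, 0.7)
  t2 <- rexp(30, 1.4); e2 <- rbinom(30, 1, 0.7)
  expect_equal(logrank_test(t1, e1, t2, e2)$statistic,
               logrank_test(3.7 * t1, e1, 3.7 * t2, e2)$statistic)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(c(t1, t2), c(e1, e2)) ~
                             rep(1:2, each = 30))
  expect_equal(logrank_test(t1, e1, t2, e2)$statistic, sd$chisq,
               tolerance = 1e-10)
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(11)
  time <- rexp(60); event <- rbinom(60, 1, 0.7)
  grp <- rbinom(60, 1, 0.5)
  ev <- cox_partial(time, event, cbind(g = grp), beta = 0)
  lr <- logrank_test(time[grp == 1], event[grp == 1],
                     time[grp == 0], event[grp == 0])
  expect_equal(ev$score[[1]], lr$observed - lr$expected, tolerance = 1e-10)
  expect_equal(ev$info[1, 1], lr$variance, tolerance = 1e-10)
  expect_equal(ev$score[[1]]^2 / ev$info[1, 1], lr$statistic,
               tolerance = 1e-10)
})

test_that("cox_fit matches coxph (Breslow) on random weighted data", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (rep in 1:3) {
    n <- 120
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
    time <- round(rexp(n, exp(0.4 * x[, 1])), 2) + 0.01  # ties on purpose
    event <- rbinom(n, 1, 0.7)
    w <- if (rep == 3) runif(n, 0.2, 2) else NULL
    cf <- cox_fit(time, event, x, weights = w)
    cp <- survival::coxph(survival::Surv(time, event) ~ x, weights = w,
                          ties = "breslow", robust = FALSE)
    expect_equal(unname(cf$coef), unname(coef(cp)), tolerance = 1e-6)
    expect_equal(unname(diag(cf$vcov)), unname(diag(vcov(cp))),
                 tolerance = 1e-5)
    # Breslow baseline cumulative hazard
    bh <- survival::basehaz(cp, centered = FALSE)
    H <- -log(survival_at(cf$baseline, bh$time))
    expect_equal(H, bh$hazard, tolerance = 1e-6)
  }
})

test_that("cox_fit recovers a known PH effect and has a monotone trace", {
  set.seed(33)
  n <- 2000
  x <- rnorm(n)
  time <- rexp(n, exp(0.7 * x))
  cens <- runif(n, 0, 3)
  cf <- cox_fit(pmin(time, cens), as.numeric(time <= cens), cbind(x = x))
  se <- sqrt(cf$vcov[1, 1])
  expect_lt(abs(cf$coef[["x"]] - 0.7), 3 * se)
  expect_monotone_trace(cf$loglik_trace, tol = 1e-10)
})

test_that("cox_fit weight-scaling and degenerate-input contracts hold", {
  set.seed(44)
  n <- 80
  x <- cbind(x = rnorm(n))
  time <- rexp(n); event <- rbinom(n, 1, 0.6)
  w <- runif(n, 0.5, 1.5)
  f1 <- cox_fit(time, event, x, weights = w)
  f2 <- cox_fit(time, event, x, weights = 2 * w)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
  expect_equal(f1$baseline$surv, f2$baseline$surv, tolerance = 1e-10)
  expect_error(cox_fit(time, event, cbind(k = rep(1, n))), "constant covariate")
  # perfect separation: flagged, coefficients capped, not an error
  xs <- c(rep(0, 20), rep(1, 20))
  ts <- c(seq(1, 2, length.out = 20), seq(10, 11, length.out = 20))
  fs <- cox_fit(ts, rep(1, 40), cbind(s = xs))
  expect_true("monotone_likelihood" %in% fs$flags)
  expect_false(fs$converged)
  expect_lte(max(abs(fs$coef)), 15)
})
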