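test_that("simulate_cure_cohort is reproducible and honours the observed-data contract", {
  spec <- cohort_spec(n = 500, seed = 99)
  a <- simulate_cure_cohort(spec)
  b <- simulate_cure_cohort(spec)
  expect_identical(a, b)
  # observed time = min(latent, censoring) for uncured, censoring for cured
  tr <- a$truth
  expect_equal(a$table$time_years,
               ifelse(tr$uncured, pmin(tr$latent_time, tr$censor_time),
                      tr$censor_time))
  expect_equal(a$table$event,
               as.integer(tr$uncured & tr$latent_time <= tr$censor_time))
})

test_that("substreams decouple generator components", {
  s1 <- cohort_spec(n = 200, seed = 5, censor_window = c(1, 8.5))
  s2 <- cohort_spec(n = 200, seed = 5, censor_window = c(2, 9.5))
  a <- simulate_cure_cohort(s1)
  b <- simulate_cure_cohort(s2)
  expect_equal(a$table$x1, b$table$x1)        # covariate stream untouched
  expect_equal(a$truth$uncured, b$truth$uncured)
  expect_equal(a$truth$latent_time, b$truth$latent_time)
  expect_false(identical(a$truth$censor_time, b$truth$censor_time))
})

test_that("saturated and empty incidence give all-uncured / all-cured cohorts", {
  up <- cohort_spec(n = 300, seed = 2,
                    incidence = list(formula = ~1,
                                     coef = c("(Intercept)" = 20)),
                    latency = list(formula = ~1, coef = numeric(0)))
  a <- simulate_cure_cohort(up)
  expect_true(all(a$truth$uncured))
  down <- cohort_spec(n = 300, seed = 2,
                      incidence = list(formula = ~1,
                                       coef = c("(Intercept)" = -20)),
                      latency = list(formula = ~1, coef = numeric(0)))
  b <- simulate_cure_cohort(down)
  expect_true(all(!b$truth$uncured))
  expect_true(all(b$table$event == 0))
})

test_that("empirical cure fraction matches the generating incidence at large n", {
  spec <- cohort_spec(n = 50000, seed = 31,
                      incidence = list(formula = ~1,
                                       coef = c("(Intercept)" = qlogis(0.21))),
                      latency = list(formula = ~1, coef = numeric(0)),
                      baseline = list(shape = 1, scale = 1.6 / log(2)),
                      censor_window = c(1, 8.5))
  coh <- simulate_cure_cohort(spec)
  se <- sqrt(0.79 * 0.21 / 50000)
  expect_lt(abs(mean(!coh$truth$uncured) - 0.79), 3 * se)
})

test_that("uncured uncensored event times follow the specified Weibull (beta = 0)", {
  spec <- cohort_spec(n = 5000, seed = 17,
                      incidence = list(formula = ~1,
                                       coef = c("(Intercept)" = 3)),
                      latency = list(formula = ~1, coef = numeric(0)),
                      baseline = list(shape = 1.4, scale = 2),
                      censor_window = c(50, 60))  # essentially no censoring
  coh <- simulate_cure_cohort(spec)
  obs <- coh$table$time_years[coh$table$event == 1]
  ks <- stats::ks.test(obs, stats::pweibull, shape = 1.4, scale = 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("KM plateau estimates the cure fraction under long follow-up", {
  # censoring window far beyond the 99.9th latency percentile
  q999 <- stats::qweibull(0.999, 1, 1.6 / log(2))
  spec <- cohort_spec(n = 10000, seed = 23,
                      incidence = list(formula = ~1,
                                       coef = c("(Intercept)" = qlogis(0.21))),
                      latency = list(formula = ~1, coef = numeric(0)),
                      baseline = list(shape = 1, scale = 1.6 / log(2)),
                      censor_window = c(q999, q999 + 5))
  coh <- simulate_cure_cohort(spec)
  km <- km_estimate(coh$table$time_years, coh$table$event)
  plateau <- km$surv[length(km$surv)]
  expect_lt(abs(plateau - 0.79), 0.02)
})

test_that("coefficient/covariate mismatches are configuration errors", {
  spec <- cohort_spec(n = 10, seed = 1,
                      incidence = list(formula = ~x1,
                                       coef = c("(Intercept)" = 0, zz = 1)))
  expect_error(simulate_cure_cohort(spec), "zz")
  spec2 <- cohort_spec(n = 10, seed = 1,
                       incidence = list(formula = ~x1,
                                        coef = c("(Intercept)" = 0)))
  expect_error(simulate_cure_cohort(spec2), "x1")
})

test_that("margin-exact simulation reproduces printed counts", {
  tab <- simulate_from_margins(n = 446, seed = 4)
  expect_equal(nrow(tab), 446)
  expect_equal(as.integer(table(tab$stage)), c(123, 314, 9))
  expect_equal(sum(tab$chemo == "1"), 384)
  expect_equal(round(100 * mean(tab$chemo == "1"), 1), 86.1)
  expect_equal(sum(tab$event_metastasis), 81)
  # group-wise exactness (counts by recurrence status)
  expect_equal(as.integer(table(tab$stage[tab$event_metastasis == 1])),
               c(15, 61, 5))
  expect_equal(nrow(simulate_from_margins(n = 0)), 0)
  bad <- table1_margins()
  bad$categorical$stage$counts[1, 1] <- 999L
  expect_error(simulate_from_margins(n = 446, margins = bad, seed = 1),
               "stage")
})

test_that("cohort specs round-trip through JSON", {
  spec <- study_spec(n = 50, seed = 77)
  path <- tempfile(fileext = ".json")
  write_cohort_spec(spec, path)
  spec2 <- read_cohort_spec(path)
  expect_equal(spec2$incidence$coef, spec$incidence$coef)
  expect_equal(spec2$latency$coef, spec$latency$coef)
  expect_equal(simulate_cure_cohort(spec2)$table,
               simulate_cure_cohort(spec)$table, tolerance = 1e-12)
})
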