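# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

# a small right-censored sample with a plateau after the last event
tiny_sample <- function(seed = 1, n = 60, cure = 0.5, rate = 1,
                        cmin = 0.5, cmax = 6) {
  set.seed(seed)
  uncured <- stats::rbinom(n, 1, 1 - cure) == 1
  latent <- ifelse(uncured, stats::rexp(n, rate), Inf)
  cens <- stats::runif(n, cmin, cmax)
  list(time = pmin(latent, cens), event = as.integer(latent <= cens),
       uncured = uncured)
}

# random small mixture-cure instance with one incidence and one latency
# covariate; used for property-style EM checks
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(40:80, 1)
  x1 <- stats::rnorm(n)
  b0 <- stats::runif(1, -1.5, 1.5)
  b1 <- stats::runif(1, -1, 1)
  beta <- stats::runif(1, -1, 1)
  pi_u <- plogis(b0 + b1 * x1)
  uncured <- stats::rbinom(n, 1, pi_u) == 1
  latent <- ifelse(uncured, stats::rweibull(n, 1.2, 1.5 * exp(-beta * x1 / 1.2)), Inf)
  cens <- stats::runif(n, 0.5, 8)
  d <- data.frame(time = pmin(latent, cens),
                  event = as.integer(latent <= cens), x1 = x1)
  if (sum(d$event) < 3 || sum(d$event == 0) < 3) return(NULL)
  d
}

# confounded two-arm cohort for matching checks
confounded_cohort <- function(seed, n = 400) {
  set.seed(seed)
  u1 <- stats::rnorm(n)
  u2 <- stats::rbinom(n, 1, 0.4)
  treat <- stats::rbinom(n, 1, plogis(-0.3 + 0.8 * u1 + 0.6 * u2))
  data.frame(id = seq_len(n), u1 = u1, u2 = u2, treat = treat)
}

# full-schema encoded patient table built from the study-emulating generator
study_table <- function(n = 350, seed = 1) {
  coh <- simulate_cure_cohort(study_spec(n = n, seed = seed))$table
  coh$event_metastasis <- coh$event
  set.seed(seed + 1)
  coh$response_3m <- factor(sample(c("CR", "PR", "SD", "PD"), n, TRUE,
                                   prob = c(0.85, 0.11, 0.02, 0.02)),
                            levels = c("CR", "PR", "SD", "PD"))
  coh$local_recurrence <- stats::rbinom(n, 1, 0.1)
  drop <- c("event", "age_gt53", "age_c", "stage_adv", "diff_low",
            "dose_std", "lars", "rate_std", "duration_std", "response_grp")
  encode_analysis_variables(coh[, setdiff(names(coh), drop)])
}

expect_monotone_trace <- function(trace, tol = 1e-8) {
  expect_true(all(diff(trace) >= -tol))
}
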