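# Semiparametric mixture cure model
#
#   S(t | x, z) = 1 - pi(z) + pi(z) * Su(t | x)
#
# pi(z) = expit(z'b) is the probability of being uncured (susceptible to
# metastatic recurrence), modelled logistically; Su(t | x) = S0(t)^exp(x'beta)
# is the latency survival of the uncured, a Cox PH model with nonparametric
# Breslow baseline S0. Estimation is by EM: the E-step computes the posterior
# probability w of being uncured for each censored subject; the M-step fits
# a weighted logistic model (responses w) and a weighted Cox model (censored
# subjects enter risk sets with weight w). The baseline carries the
# zero-tail constraint, S0(t) = 0 beyond the last event time, which makes
# the cure fraction identifiable.
#
# Likelihood convention (discrete Breslow/Poisson form): an event at t
# contributes log pi + log dH0(t) + x'beta - H0(t) exp(x'beta) with H0(t)
# including the jump at t itself; a censored subject contributes
# log(1 - pi + pi * exp(-H0(t) exp(x'beta))). Under this convention the
# weighted Breslow baseline profiles the complete-data likelihood exactly,
# so the EM has a nondecreasing observed-data log-likelihood.

#' E-step posterior uncured weights
#'
#' For subjects with an event, the posterior probability of being uncured
#' is 1. For a subject censored at time t it is
#' `pi * Su / (1 - pi + pi * Su)` with `Su = S0(t)^exp(x beta)`. When the
#' denominator is 0 (pi = 1 while Su = 0: a subject forced uncured but
#' censored after the last event, a contradiction under the zero-tail
#' constraint) the weight is set to 0 and flagged via the `"guarded"`
#' attribute.
#'
#' @param b incidence coefficients (including intercept).
#' @param beta latency coefficients.
#' @param S0 baseline latency survival, a [step_surv] (tail `"zero"`).
#' @param time,event observed follow-up data.
#' @param z incidence design matrix (with intercept column).
#' @param x latency design matrix (no intercept; may have 0 columns).
#' @return numeric vector of weights in `[0, 1]`, 1 for events.
#' @export
estep_weights <- function(b, beta, S0, time, event, z, x) {
  pi_u <- expit(drop(as.matrix(z) %*% b))
  eta <- if (length(beta)) drop(as.matrix(x) %*% beta) else rep(0, length(time))
  su <- exp(-cumhaz_at(S0, time) * exp(eta))   # hazard scale: no precision loss
  num <- pi_u * su
  den <- 1 - pi_u + num
  w <- ifelse(den > 1e-12, num / den, 0)
  guarded <- den <= 1e-12 & event == 0
  w[event == 1] <- 1
  structure(pmin(pmax(w, 0), 1), guarded = any(guarded))
}

#' Incidence M-step: weighted logistic fit with fractional responses
#'
#' Maximizes the weighted Bernoulli likelihood with the posterior uncured
#' weights as (fractional) responses. Thin wrapper around [logit_fit()];
#' see there for the separation fallback and capping behaviour.
#'
#' @param z incidence design matrix (with intercept).
#' @param w posterior uncured weights in `[0, 1]`.
#' @param start optional starting coefficients.
#' @return list as returned by [logit_fit()].
#' @export
mstep_incidence <- function(z, w, start = NULL) {
  logit_fit(z, w, start = start)
}

#' Latency M-step: weighted Cox fit with zero-tail baseline
#'
#' Weighted Cox PH fit in which subjects with events carry weight 1 and
#' censored subjects carry their posterior uncured weight in the risk sets.
#' The Breslow baseline survival is returned with the zero-tail constraint
#' (0 beyond the last event time).
#'
#' @param time,event observed follow-up data.
#' @param x latency design matrix (no intercept; may have 0 columns).
#' @param w posterior uncured weights (1 for events).
#' @param start optional starting coefficients.
#' @return a `cure_cox` fit (see [cox_fit()]) with zero-tail baseline.
#' @export
mstep_latency <- function(time, event, x, w, start = NULL) {
  wt <- ifelse(event == 1, 1, w)
  fit <- cox_fit(time, event, x, weights = wt, init = start, zero_tail = TRUE)
  # ascent guard (needed for EM monotonicity when the Newton iteration hits
  # the separation cap): never return a point below the starting value of
  # the weighted partial likelihood
  if (!is.null(start) && length(start)) {
    ll0 <- cox_partial(time, event, x, wt, start)$loglik
    if (fit$loglik < ll0 - 1e-12) {
      fit <- cox_fit(time, event, x, weights = wt, init = start,
                     max_iter = 0L, zero_tail = TRUE)
      fit$flags <- unique(c(fit$flags, "kept_start"))
    }
  }
  fit
}

#' Observed-data log-likelihood of the mixture cure model
#'
#' Events contribute `log pi + log dH0(t) + x beta - H0(t) exp(x beta)`
#' (discrete Breslow convention, `H0(t)` including the jump at `t`);
#' censored subjects contribute `log(1 - pi + pi Su(t|x))`, which is
#' `log(1 - pi)` beyond the last event time under the zero-tail
#' constraint. Logs are floored at `1e-300` to guard against `-Inf`.
#'
#' @inheritParams estep_weights
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(b, beta, S0, time, event, z, x) {
  pi_u <- expit(drop(as.matrix(z) %*% b))
  eta <- if (length(beta)) drop(as.matrix(x) %*% beta) else rep(0, length(time))
  ll <- numeric(length(time))
  ev <- event == 1
  if (any(ev)) {
    if (is.null(S0$hazard)) stop("S0 must carry Breslow hazard increments")
    jump <- S0$hazard[match(time[ev], S0$time)]
    if (any(is.na(jump))) stop("event time with no baseline hazard jump")
    H <- cumhaz_at(S0, time[ev])
    ll[ev] <- log(pmax(pi_u[ev], 1e-300)) + log(pmax(jump, 1e-300)) +
      eta[ev] - H * exp(eta[ev])
  }
  if (any(!ev)) {
    su <- exp(-cumhaz_at(S0, time[!ev]) * exp(eta[!ev]))
    ll[!ev] <- log(pmax(1 - pi_u[!ev] + pi_u[!ev] * su, 1e-300))
  }
  sum(ll)
}

#' Low-level EM fitter for the mixture cure model
#'
#' Matrix-interface engine behind [curemix()]. Alternates
#' [estep_weights()], [mstep_incidence()] and [mstep_latency()] until the
#' observed-data log-likelihood changes by less than `tol`.
#'
#' @param time,event follow-up times (years) and 0/1 event indicators.
#' @param z incidence design matrix with exactly one intercept column.
#' @param x latency design matrix without intercept (may have 0 columns).
#' @param tol absolute convergence tolerance on the observed-data
#'   log-likelihood (default `1e-7`).
#' @param max_iter maximum EM iterations (default 500).
#' @param init optional list with components `b` and `beta`.
#' @param pi_fixed optional fixed uncured probability: `pi_fixed = 1`
#'   forces every subject uncured (the model then reduces to an ordinary
#'   Cox PH fit); the incidence model is not estimated.
#' @return object of class `curemix`; see [curemix()].
#' @export
curemix_fit <- function(time, event, z, x = NULL, tol = 1e-7,
                        max_iter = 500L, init = NULL, pi_fixed = NULL) {
  z <- as.matrix(z)
  x <- if (is.null(x)) matrix(numeric(0), length(time), 0) else as.matrix(x)
  n <- length(time)
  stopifnot(nrow(z) == n, nrow(x) == n, all(event %in% c(0, 1)))
  if (any(time < 0)) stop("negative follow-up times")
  if (sum(event) < 1) stop("at least one event is required")
  if (all(event == 1)) stop("at least one censored subject is required")
  ic <- which(apply(z, 2L, function(col) all(col == 1)))
  if (length(ic) != 1L)
    stop("incidence design must contain exactly one intercept column")
  last_event <- max(time[event == 1])
  if (!any(event == 0 & time >= last_event))
    warning("no censored subject at or after the last event time; ",
            "the cure fraction is weakly identified", call. = FALSE)

  fixed_pi <- !is.null(pi_fixed)
  if (fixed_pi) {
    stopifnot(pi_fixed > 0, pi_fixed <= 1)
    b <- rep(0, ncol(z)); b[ic] <- logit(min(pi_fixed, 1 - 1e-12))
    names(b) <- colnames(z)
  }

  # initialization: logistic fit of the event indicator; Cox fit on all data
  b <- if (fixed_pi) b else {
    ini <- init$b %||% suppressWarnings(logit_fit(z, event)$coef)
    stats::setNames(ini, colnames(z))
  }
  lat <- mstep_latency(time, event, x, rep(1, n), start = init$beta)
  beta <- lat$coef
  S0 <- lat$baseline
  guard_note <- FALSE

  ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- if (fixed_pi && pi_fixed == 1) rep(1, n) else
      estep_weights(b, beta, S0, time, event, z, x)
    guard_note <- guard_note || isTRUE(attr(w, "guarded"))
    if (!fixed_pi) {
      inc <- suppressWarnings(mstep_incidence(z, w, start = b))
      b <- inc$coef
    }
    lat <- mstep_latency(time, event, x, w, start = if (length(beta)) beta else NULL)
    beta <- lat$coef
    S0 <- lat$baseline
    ll_new <- observed_loglik(b, beta, S0, time, event, z, x)
    if (is.nan(ll_new))
      stop("NaN observed-data log-likelihood at iteration ", iter,
           "; b = ", paste(signif(b, 4), collapse = ", "),
           "; beta = ", paste(signif(beta, 4), collapse = ", "))
    trace <- c(trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }
  w <- if (fixed_pi && pi_fixed == 1) rep(1, n) else
    estep_weights(b, beta, S0, time, event, z, x)

  structure(list(
    b = b, beta = beta, S0 = S0, w = as.numeric(w),
    loglik = ll, loglik_trace = trace,
    converged = converged, n_iter = iter,
    n = n, n_events = sum(event),
    pi_fixed = pi_fixed, guarded_weights = guard_note,
    incidence_flags = if (!fixed_pi) attr(b, "flags") else NULL,
    time = time, event = event, z = z, x = x
  ), class = "curemix")
}

#' Fit a semiparametric mixture cure model
#'
#' Fits `S(t|x,z) = 1 - pi(z) + pi(z) Su(t|x)` by EM: a logistic incidence
#' model for the probability `pi(z)` of being uncured (susceptible) and a
#' semiparametric Cox PH latency model `Su(t|x) = S0(t)^exp(x beta)` for
#' the time to event among the uncured, with the Breslow baseline under
#' the zero-tail constraint.
#'
#' The left-hand side of `formula` must be `cbind(time, event)` with time
#' in years and a 0/1 event indicator; its right-hand side gives the
#' latency covariates. `cureform` is a one-sided formula for the incidence
#' covariates (an intercept is always included).
#'
#' @param formula model formula `cbind(time, event) ~ latency covariates`.
#' @param cureform one-sided formula of incidence covariates.
#' @param data data frame containing all variables.
#' @param tol,max_iter,init,pi_fixed passed to [curemix_fit()].
#' @return object of class `curemix` with components `b` (incidence
#'   log-odds coefficients of being uncured), `beta` (latency log hazard
#'   ratios), `S0` (baseline latency survival, [step_surv] with zero
#'   tail), `w` (posterior uncured weights; 1 for events), `loglik_trace`,
#'   `converged`, and the model frames needed by `predict()`.
#' @seealso [predict.curemix()], [cure_bootstrap()], [summary.curemix()]
#' @examples
#' spec <- cohort_spec(n = 300, seed = 7)
#' coh <- simulate_cure_cohort(spec)$table
#' fit <- curemix(cbind(time_years, event) ~ x1, cureform = ~ x1, data = coh)
#' coef(fit)
#' @export
curemix <- function(formula, cureform, data, tol = 1e-7, max_iter = 500L,
                    init = NULL, pi_fixed = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.null(dim(y)) || ncol(y) != 2L)
    stop("left-hand side must be cbind(time, event)")
  time <- as.numeric(y[, 1L]); event <- as.numeric(y[, 2L])
  lat_terms <- stats::delete.response(stats::terms(formula, data = data))
  x <- stats::model.matrix(lat_terms, mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  inc_terms <- stats::terms(cureform, data = data)
  z <- stats::model.matrix(inc_terms, stats::model.frame(cureform, data,
                                                         na.action = stats::na.fail))
  fit <- curemix_fit(time, event, z, x, tol = tol, max_iter = max_iter,
                     init = init, pi_fixed = pi_fixed)
  fit$call <- match.call()
  fit$formula <- formula
  fit$cureform <- cureform
  fit$lat_terms <- lat_terms
  fit$inc_terms <- inc_terms
  fit$data <- data
  fit
}
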