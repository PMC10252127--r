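#' @export
print.curemix <- function(x, ...) {
  cat("Semiparametric mixture cure model (EM", x$n_iter, "iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  cat(sprintf("  n = %d, events = %d, observed-data loglik = %.4f\n",
              x$n, x$n_events, x$loglik))
  cat(sprintf("  mean cure probability = %.3f\n",
              mean(predict_cure_probability(x))))
  cat("\nIncidence (log-odds of being uncured):\n")
  print(round(x$b, 4))
  if (length(x$beta)) {
    cat("\nLatency (log hazard ratios):\n")
    print(round(x$beta, 4))
  }
  invisible(x)
}

#' @export
coef.curemix <- function(object, ...) {
  c(stats::setNames(object$b, paste0("incidence.", names(object$b))),
    if (length(object$beta))
      stats::setNames(object$beta, paste0("latency.", names(object$beta))))
}

#' @export
logLik.curemix <- function(object, ...) {
  structure(object$loglik, df = length(object$b) + length(object$beta),
            nobs = object$n, class = "logLik")
}

new_designs <- function(object, newdata) {
  if (is.null(newdata)) return(list(z = object$z, x = object$x))
  z <- stats::model.matrix(object$inc_terms,
                           stats::model.frame(object$inc_terms, newdata,
                                              na.action = stats::na.fail))
  x <- stats::model.matrix(object$lat_terms,
                           stats::model.frame(object$lat_terms, newdata,
                                              na.action = stats::na.fail))
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  list(z = z, x = x)
}

#' Predicted cure probabilities
#'
#' Per-subject cure probability `1 - pi(z) = 1 - expit(z b)`. Population
#' summaries (e.g. the cohort cure fraction) are means of these
#' per-subject values.
#'
#' @param fit a `curemix` object.
#' @param newdata optional data frame; default is the fitted data.
#' @return vector of cure probabilities in `[0, 1]`.
#' @export
predict_cure_probability <- function(fit, newdata = NULL) {
  d <- new_designs(fit, newdata)
  1 - expit(drop(d$z %*% fit$b))
}

#' Latency survival curve of an uncured subject
#'
#' `Su(t|x) = S0(t)^exp(x beta)` for one covariate row.
#'
#' @param fit a `curemix` object.
#' @param x_new latency covariate vector (fitted scale); default all 0
#'   (the baseline).
#' @return a [step_surv] with zero tail.
#' @export
uncured_survival <- function(fit, x_new = NULL) {
  eta <- if (length(fit$beta))
    sum(as.numeric(x_new %||% rep(0, length(fit$beta))) * fit$beta) else 0
  step_surv(fit$S0$time, fit$S0$surv^exp(eta), tail = "zero")
}

#' Median event time of uncured subjects
#'
#' Smallest baseline knot at which `Su(t|x)` is at or below 0.5. Returns
#' `NA` flagged `defined = FALSE` if the curve never crosses 0.5 (cannot
#' happen for a fitted zero-tail baseline, but can for externally supplied
#' curves).
#'
#' @param fit a `curemix` object, or a [step_surv] giving `Su` directly.
#' @param x_new latency covariate vector (ignored when `fit` is a curve).
#' @return median time in years (see [median_from_curve()]).
#' @export
median_uncured_time <- function(fit, x_new = NULL) {
  curve <- if (inherits(fit, "step_surv")) fit else uncured_survival(fit, x_new)
  median_from_curve(curve)
}

#' Individualized marginal survival curve
#'
#' The mixture survival `S(t|x,z) = 1 - pi(z) + pi(z) Su(t|x)` for one
#' subject; the curve plateaus at the cure probability `1 - pi(z)`.
#'
#' @param fit a `curemix` object.
#' @param z_new incidence covariate row (fitted scale, including
#'   intercept), or `NULL` for the baseline subject.
#' @param x_new latency covariate row.
#' @return a [step_surv] (plateau tail at `1 - pi`); the uncured
#'   conditional curve is available via [uncured_survival()].
#' @export
predict_marginal_survival <- function(fit, z_new = NULL, x_new = NULL) {
  if (is.null(z_new)) { z_new <- rep(0, length(fit$b)); z_new[1] <- 1 }
  pi_u <- expit(sum(as.numeric(z_new) * fit$b))
  su <- uncured_survival(fit, x_new)
  vals <- 1 - pi_u + pi_u * su$surv
  # just beyond the last event time Su drops to 0 (zero tail), so the
  # marginal curve reaches its floor 1 - pi there; an epsilon knot makes
  # the plateau explicit
  tl <- su$time[length(su$time)]
  step_surv(c(su$time, tl + 1e-8 * max(1, tl)), c(vals, 1 - pi_u),
            tail = "plateau")
}

#' Pointwise mean of individualized marginal curves over a cohort
#'
#' Ensemble summary used to compare the mixture cure model against an
#' ordinary Cox fit: the empirical mean over subjects of the
#' individualized curves `S(t|x_i,z_i)`, evaluated on the baseline knots.
#'
#' @param fit a `curemix` object.
#' @param newdata optional data frame (default: fitted data).
#' @return a [step_surv].
#' @export
marginal_mean_curve <- function(fit, newdata = NULL) {
  d <- new_designs(fit, newdata)
  pi_u <- expit(drop(d$z %*% fit$b))
  eta <- if (length(fit$beta)) drop(d$x %*% fit$beta) else rep(0, nrow(d$z))
  s0 <- fit$S0$surv
  m <- vapply(seq_along(s0), function(k) {
    mean(1 - pi_u + pi_u * s0[k]^exp(eta))
  }, numeric(1))
  tl <- fit$S0$time[length(fit$S0$time)]
  step_surv(c(fit$S0$time, tl + 1e-8 * max(1, tl)),
            c(m, mean(1 - pi_u)), tail = "plateau")
}

#' Predict method for mixture cure fits
#'
#' @param object a `curemix` object.
#' @param newdata optional data frame.
#' @param type `"cure"` (cure probabilities), `"uncured"` (probabilities
#'   of being uncured), `"median"` (per-subject median uncured event
#'   time), or `"survival"` (list of individualized marginal
#'   [step_surv] curves).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.curemix <- function(object, newdata = NULL,
                            type = c("cure", "uncured", "median", "survival"),
                            ...) {
  type <- match.arg(type)
  d <- new_designs(object, newdata)
  switch(type,
    cure = predict_cure_probability(object, newdata),
    uncured = 1 - predict_cure_probability(object, newdata),
    median = vapply(seq_len(nrow(d$x)), function(i)
      as.numeric(median_uncured_time(object, d$x[i, ])), numeric(1)),
    survival = lapply(seq_len(nrow(d$z)), function(i)
      predict_marginal_survival(object, d$z[i, ], d$x[i, ]))
  )
}

#' Plot individualized survival curves of a mixture cure fit
#'
#' Spaghetti plot of per-subject marginal curves with their pointwise mean
#' overlaid, in the style of individualized model-comparison figures.
#'
#' @param x a `curemix` object.
#' @param newdata optional data frame (default fitted data; at most
#'   `max_curves` subjects drawn).
#' @param max_curves number of individual curves to draw.
#' @param ... passed to `plot`.
#' @return invisibly, the mean curve.
#' @export
plot.curemix <- function(x, newdata = NULL, max_curves = 100L, ...) {
  d <- new_designs(x, newdata)
  n <- nrow(d$z)
  idx <- if (n > max_curves) seq(1L, n, length.out = max_curves) else seq_len(n)
  mc <- marginal_mean_curve(x, newdata)
  plot(NA, xlim = c(0, max(x$S0$time)), ylim = c(0, 1),
       xlab = "Years", ylab = "Marginal survival S(t|x,z)", ...)
  for (i in round(idx)) {
    ci <- predict_marginal_survival(x, d$z[i, ], d$x[i, ])
    graphics::lines(stats::stepfun(ci$time, c(1, ci$surv)), do.points = FALSE,
                    col = grDevices::adjustcolor("firebrick", 0.2))
  }
  graphics::lines(stats::stepfun(mc$time, c(1, mc$surv)), do.points = FALSE,
                  lwd = 2)
  invisible(mc)
}

#' Simulate event data from a fitted mixture cure model
#'
#' Draws cure status from the fitted incidence model and, for uncured
#' subjects, an event time from the fitted discrete baseline raised to
#' `exp(x beta)` (inverse-CDF on the baseline knots). Times are
#' administratively censored at the largest baseline knot.
#'
#' @param object a `curemix` object.
#' @param nsim number of replicate data sets.
#' @param seed optional RNG seed.
#' @param newdata optional covariate data frame (default fitted data).
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `time`, `event`.
#' @export
simulate.curemix <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- new_designs(object, newdata)
  n <- nrow(d$z)
  pi_u <- expit(drop(d$z %*% object$b))
  eta <- if (length(object$beta)) drop(d$x %*% object$beta) else rep(0, n)
  knots <- object$S0$time
  s0 <- object$S0$surv
  tmax <- max(knots)
  lapply(seq_len(nsim), function(s) {
    uncured <- stats::rbinom(n, 1, pi_u) == 1
    u <- stats::runif(n)
    # inverse CDF: first knot where Su drops below u (Su has zero tail)
    su <- outer(exp(eta), log(pmax(s0, 1e-300)))  # n x k of log Su
    time <- rep(tmax, n)
    event <- rep(0L, n)
    for (i in which(uncured)) {
      hit <- which(exp(su[i, ]) <= u[i])
      if (length(hit)) { time[i] <- knots[hit[1L]]; event[i] <- 1L }
    }
    data.frame(time = time, event = event)
  })
}

#' Summary method for mixture cure fits
#'
#' Reports incidence coefficients as odds ratios of being uncured (OR > 1:
#' higher susceptibility to the event) and latency coefficients as hazard
#' ratios. If a [cure_bootstrap()] object is supplied, bootstrap SEs,
#' percentile 95% CIs and two-sided Wald p-values are attached.
#'
#' @param object a `curemix` object.
#' @param boot optional `curemix_boot` object from [cure_bootstrap()].
#' @param ... unused.
#' @return object of class `summary.curemix` with data frames `incidence`
#'   and `latency`.
#' @export
summary.curemix <- function(object, boot = NULL, ...) {
  inc <- data.frame(coef = object$b, OR = exp(object$b),
                    row.names = names(object$b))
  lat <- if (length(object$beta))
    data.frame(coef = object$beta, HR = exp(object$beta),
               row.names = names(object$beta))
  else data.frame(coef = numeric(0), HR = numeric(0))
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "curemix_boot"))
    inc$SD <- boot$se[seq_along(object$b)]
    inc$ci_lo <- exp(boot$ci[seq_along(object$b), 1L])
    inc$ci_hi <- exp(boot$ci[seq_along(object$b), 2L])
    inc$p <- boot$p[seq_along(object$b)]
    k <- length(object$b) + seq_along(object$beta)
    if (length(object$beta)) {
      lat$SD <- boot$se[k]
      lat$ci_lo <- exp(boot$ci[k, 1L])
      lat$ci_hi <- exp(boot$ci[k, 2L])
      lat$p <- boot$p[k]
    }
  }
  structure(list(incidence = inc, latency = lat,
                 cure_probability = mean(predict_cure_probability(object)),
                 median_uncured = as.numeric(median_uncured_time(
                   object, colMeans(object$x))),
                 converged = object$converged, n = object$n,
                 n_events = object$n_events, boot = !is.null(boot)),
            class = "summary.curemix")
}

#' @export
print.summary.curemix <- function(x, digits = 4, ...) {
  cat(sprintf("Mixture cure model: n = %d, events = %d%s\n", x$n, x$n_events,
              if (x$converged) "" else " (EM not converged)"))
  cat(sprintf("Mean cure probability: %.1f%%; median uncured event time: %.2f years\n\n",
              100 * x$cure_probability, x$median_uncured))
  cat("Incidence model (OR of being uncured):\n")
  print(round(x$incidence, digits))
  if (nrow(x$latency)) {
    cat("\nLatency model (HR):\n")
    print(round(x$latency, digits))
  }
  invisible(x)
}
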