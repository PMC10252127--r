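# Classical right-censored survival machinery: weighted Kaplan-Meier with
# Greenwood variance and the two-sample log-rank test. Weights enter risk
# sets and event counts multiplicatively (fractional subjects), the
# convention the mixture cure EM relies on.

check_sample <- function(time, event, weights) {
  n <- length(time)
  if (length(event) != n) stop("time and event must have equal length")
  if (!n) stop("at least one subject is required")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and nonnegative")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0/1")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stop("weights must be nonnegative, one per subject")
  weights
}

#' Kaplan-Meier estimator with Greenwood variance
#'
#' Weighted product-limit estimator. At tied times events precede
#' censorings (the standard convention); knots are placed at event times
#' only. With `weights` supplied, risk sets and event counts are weighted
#' sums, so fractional subjects are supported.
#'
#' @param time follow-up times (years), nonnegative.
#' @param event 0/1 event indicators.
#' @param weights optional nonnegative per-subject weights (default 1).
#' @return a [step_surv] with Greenwood variance, weighted risk-set sizes
#'   and event counts at each knot.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(time, event, weights = NULL) {
  w <- check_sample(time, event, weights)
  ev <- event == 1 & w > 0
  if (!any(ev)) {
    return(step_surv(numeric(0), numeric(0), var = numeric(0),
                     n_risk = numeric(0), n_event = numeric(0)))
  }
  ord <- order(time)
  t_s <- time[ord]; w_s <- w[ord]; e_s <- as.numeric(ev)[ord]
  tev <- unique(t_s[e_s == 1])
  # weighted risk set (time >= t) and event mass at each event time
  first <- which(!duplicated(t_s))
  n_risk <- revcumsum(w_s)[first[match(tev, t_s[first])]]
  grp <- match(t_s, tev)
  dful <- rowsum((w_s * e_s)[!is.na(grp)], grp[!is.na(grp)])
  d <- numeric(length(tev)); d[as.integer(rownames(dful))] <- dful
  s <- cumprod(1 - d / n_risk)
  gw <- d / (n_risk * pmax(n_risk - d, .Machine$double.xmin))
  v <- s^2 * cumsum(gw)
  v[s == 0] <- 0
  step_surv(tev, s, var = v, n_risk = n_risk, n_event = d)
}

#' Two-sample log-rank test
#'
#' Standard (unweighted-score) log-rank test for right-censored data:
#' observed-minus-expected events in group A summed over event times, with
#' the hypergeometric variance; chi-square statistic on 1 df and two-sided
#' p-value. A comparison with zero total variance (e.g. no events) returns
#' statistic 0 and p = 1.
#'
#' @param timeA,eventA follow-up times and 0/1 event flags, group A.
#' @param timeB,eventB likewise for group B.
#' @return list with `statistic`, `p_value`, `observed`, `expected` (group
#'   A), and `variance`.
#' @export
logrank_test <- function(timeA, eventA, timeB, eventB) {
  check_sample(timeA, eventA, NULL)
  check_sample(timeB, eventB, NULL)
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c(1L, 0L), c(length(timeA), length(timeB)))
  tev <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in tev) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == 1L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp == 1L)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o - e)^2 / v else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = o, expected = e, variance = v)
}
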