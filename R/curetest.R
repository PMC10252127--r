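# Nonparametric test of cure probability at a follow-up horizon, under the
# mixture-cure framework: the Kaplan-Meier estimate at the horizon tau is
# the nonparametric estimate of the probability of being event-free at tau
# (the plateau value estimates the cure fraction under sufficient
# follow-up). The one-sided test of H0: cure probability <= c0 against
# H1: > c0 uses a normal approximation on the complementary log-log scale
# by default (delta-method SE from the Greenwood variance), with a
# documented exact binomial bound in small or boundary samples:
# conditioning on the subjects whose status at tau is known (failed by tau,
# or observed event-free beyond tau), the number event-free is
# stochastically bounded by Binomial(n_known, c0) under H0, giving
# p = P(Bin(n_known, c0) >= k). The binomial bound is also the c0 = 0
# boundary rule: p = 0 as soon as anyone is observed event-free beyond tau,
# else p = 1.

#' Nonparametric test of cure probability at a horizon
#'
#' Tests `H0: S(tau) <= c0` against `H1: S(tau) > c0`, where `S(tau)` is
#' estimated by the Kaplan-Meier curve at `tau`. Larger estimates give
#' smaller one-sided p-values.
#'
#' @param time,event right-censored follow-up data (years).
#' @param tau horizon (years); must be within the follow-up range with
#'   subjects still at risk.
#' @param c0 null cure level in `[0, 1)`.
#' @param scale `"cloglog"` (default) or `"identity"` for the normal
#'   approximation. Boundary cases (`c0 = 0`, estimate 1, or zero
#'   Greenwood SE) fall back to the exact binomial bound described above.
#' @return object of class `cure_test`: `tau`, `c0`, `estimate` (KM at
#'   tau), `se` (Greenwood), `z`, `p` (one-sided), `n_at_risk`, `method`.
#' @examples
#' ct <- cure_probability_test(c(1, 2, 3, 6, 7, 8), c(1, 1, 1, 0, 0, 0),
#'                             tau = 5, c0 = 0.2)
#' ct$p
#' @export
cure_probability_test <- function(time, event, tau, c0,
                                  scale = c("cloglog", "identity")) {
  scale <- match.arg(scale)
  check_sample(time, event, NULL)
  stopifnot(tau >= 0, c0 >= 0, c0 < 1)
  n_at_risk <- sum(time >= tau)
  if (n_at_risk == 0)
    stop("no subjects at risk at tau = ", tau, "; choose a smaller horizon")
  km <- km_estimate(time, event)
  est <- survival_at(km, tau)
  v <- if (length(km$time)) {
    idx <- findInterval(tau, km$time)
    if (idx == 0) 0 else km$var[idx]
  } else 0
  se <- sqrt(v)
  # subjects whose status at tau is known: failed by tau, or event-free
  # through tau (censored at exactly tau still counts as event-free there)
  k_free <- sum(time > tau) + sum(time == tau & event == 0)
  n_known <- k_free + sum(event == 1 & time <= tau)
  boundary <- c0 == 0 || est >= 1 || se == 0 || est <= 0
  if (boundary) {
    p <- stats::pbinom(k_free - 1L, n_known, c0, lower.tail = FALSE)
    z <- NA_real_
    method <- "binomial_bound"
  } else if (scale == "identity") {
    z <- (est - c0) / se
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal_identity"
  } else {
    # g(S) = log(-log S) is decreasing in S; H1: S > c0 <=> g(est) < g(c0)
    se_g <- se / abs(est * log(est))
    z <- (log(-log(c0)) - log(-log(est))) / se_g
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal_cloglog"
  }
  structure(list(tau = tau, c0 = c0, estimate = est, se = se, z = z, p = p,
                 n_at_risk = n_at_risk, method = method),
            class = "cure_test")
}

#' @export
print.cure_test <- function(x, ...) {
  cat(sprintf(
    "Cure probability test at tau = %g y: KM = %.4f (SE %.4f), H1: > %g\n",
    x$tau, x$estimate, x$se, x$c0))
  cat(sprintf("  one-sided p = %.4g (%s), %d at risk at tau\n",
              x$p, x$method, x$n_at_risk))
  invisible(x)
}

#' Profile of cure-probability tests over horizon and null-level grids
#'
#' Runs [cure_probability_test()] for every `(tau, c0)` pair. Cells whose
#' test errors (e.g. nobody at risk at `tau`) are returned with missing
#' entries and the failure reason; no multiplicity adjustment is applied.
#'
#' @param time,event right-censored follow-up data.
#' @param taus horizon grid (default yearly 1-8).
#' @param c0s null cure levels (default 0, 0.7, 0.8).
#' @param scale passed to [cure_probability_test()].
#' @return long-format data frame (`tau`, `c0`, `estimate`, `se`, `p`,
#'   `n_at_risk`, `reason`), CSV-ready.
#' @export
cure_test_profile <- function(time, event, taus = 1:8,
                              c0s = c(0, 0.7, 0.8),
                              scale = c("cloglog", "identity")) {
  scale <- match.arg(scale)
  grid <- expand.grid(tau = taus, c0 = c0s, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) {
    return(data.frame(tau = numeric(0), c0 = numeric(0),
                      estimate = numeric(0), se = numeric(0), p = numeric(0),
                      n_at_risk = integer(0), reason = character(0)))
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- tryCatch(
      cure_probability_test(time, event, grid$tau[i], grid$c0[i], scale),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(tau = grid$tau[i], c0 = grid$c0[i], estimate = NA_real_,
                 se = NA_real_, p = NA_real_, n_at_risk = NA_integer_,
                 reason = res)
    } else {
      data.frame(tau = res$tau, c0 = res$c0, estimate = res$estimate,
                 se = res$se, p = res$p, n_at_risk = res$n_at_risk,
                 reason = "")
    }
  })
  do.call(rbind, rows)
}
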