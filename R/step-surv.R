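#' Right-continuous step survival function
#'
#' Container for a nonparametric survival curve: strictly increasing knot
#' times with the survival value holding from each knot (inclusive) up to
#' the next. The value before the first knot is 1. Beyond the last knot the
#' curve either stays at its last value (`tail = "plateau"`, the
#' Kaplan-Meier convention) or is 0 (`tail = "zero"`, the zero-tail
#' constraint used for the latency baseline of a mixture cure model).
#'
#' @param time strictly increasing nonnegative knot times (years).
#' @param surv survival values in `[0, 1]`, nonincreasing.
#' @param var optional Greenwood variance of `surv` at each knot.
#' @param hazard optional discrete hazard jump at each knot (Breslow
#'   increments for a baseline curve).
#' @param n_risk,n_event optional (weighted) risk-set size and event count
#'   at each knot.
#' @param tail `"plateau"` or `"zero"` (see Details).
#' @return an object of class `step_surv`.
#' @examples
#' s <- step_surv(c(1, 2, 3), c(2/3, 1/3, 0))
#' survival_at(s, c(0.5, 1, 2.9, 10))
#' @export
step_surv <- function(time, surv, var = NULL, hazard = NULL,
                      n_risk = NULL, n_event = NULL,
                      tail = c("plateau", "zero")) {
  tail <- match.arg(tail)
  stopifnot(length(time) == length(surv))
  if (length(time)) {
    if (any(diff(time) <= 0)) stop("knot times must be strictly increasing")
    if (any(time < 0)) stop("knot times must be nonnegative")
    if (any(surv < -1e-12 | surv > 1 + 1e-12)) stop("survival values must lie in [0, 1]")
    if (any(diff(surv) > 1e-12)) stop("survival values must be nonincreasing")
    surv <- pmin(pmax(surv, 0), 1)
  }
  structure(list(time = as.numeric(time), surv = as.numeric(surv),
                 var = var, hazard = hazard,
                 n_risk = n_risk, n_event = n_event, tail = tail),
            class = "step_surv")
}

#' Evaluate a step survival curve
#'
#' Right-continuous evaluation: at a knot the post-jump value applies.
#'
#' @param curve a [step_surv] object.
#' @param t nonnegative times (vectorized).
#' @return survival probabilities at `t`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "step_surv"))
  if (any(t < 0)) stop("evaluation times must be nonnegative")
  if (!length(curve$time)) return(rep(1, length(t)))
  idx <- findInterval(t, curve$time)      # 0 => before first knot
  out <- c(1, curve$surv)[idx + 1L]
  if (curve$tail == "zero") out[t > curve$time[length(curve$time)]] <- 0
  out
}

#' @export
print.step_surv <- function(x, ...) {
  cat(sprintf("Step survival curve: %d knots, tail = %s\n",
              length(x$time), x$tail))
  if (length(x$time)) {
    cat(sprintf("  time range [%.4g, %.4g], final survival %.4g\n",
                x$time[1], x$time[length(x$time)], x$surv[length(x$surv)]))
  }
  invisible(x)
}

#' @export
as.data.frame.step_surv <- function(x, ...) {
  d <- data.frame(time = x$time, survival = x$surv)
  if (!is.null(x$var)) d$variance <- x$var
  d
}

#' Lossless CSV export of a step survival curve
#'
#' Writes columns `time,survival[,variance]` at full precision so the curve
#' re-parses to identical values.
#'
#' @param curve a [step_surv] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_step_surv_csv <- function(curve, path) {
  d <- as.data.frame(curve)
  utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate the cumulative hazard of a baseline step curve
#'
#' Right-continuous evaluation of `H(t)` from the stored Breslow hazard
#' increments (falling back to `-log(surv)` when no increments are
#' stored). Computing on the hazard scale avoids the loss of precision
#' that `-log(exp(-H))` suffers when `H` is below about `1e-16` —
#' material when the hazard is later scaled by a large `exp(x beta)`.
#' Beyond the last knot the value is `Inf` for `tail = "zero"` curves.
#'
#' @param curve a [step_surv].
#' @param t nonnegative times (vectorized).
#' @return cumulative hazard at `t`.
#' @export
cumhaz_at <- function(curve, t) {
  stopifnot(inherits(curve, "step_surv"))
  if (any(t < 0)) stop("evaluation times must be nonnegative")
  if (!length(curve$time)) return(rep(0, length(t)))
  H <- if (!is.null(curve$hazard)) cumsum(curve$hazard)
  else -log(pmax(curve$surv, 1e-300))
  idx <- findInterval(t, curve$time)
  out <- c(0, H)[idx + 1L]
  if (curve$tail == "zero") out[t > curve$time[length(curve$time)]] <- Inf
  out
}

# first knot time at which the curve is <= 0.5; NA if never crossed
#' Median event time of a step survival curve
#'
#' Smallest knot time at which survival is at or below one half. Returns
#' `NA` (with attribute `defined = FALSE`) when the curve never crosses 0.5,
#' which is flagged rather than silent.
#'
#' @param curve a [step_surv] object.
#' @return the median time, or `NA` with attribute `defined = FALSE`.
#' @export
median_from_curve <- function(curve) {
  stopifnot(inherits(curve, "step_surv"))
  hit <- which(curve$surv <= 0.5)
  if (!length(hit)) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(curve$time[hit[1L]], defined = TRUE)
}
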