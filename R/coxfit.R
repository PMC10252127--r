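# Weighted Cox proportional-hazards engine: Newton-Raphson maximizer of the
# Breslow-tie weighted partial likelihood with step-halving (monotone
# likelihood trace), plus the weighted Breslow baseline. This is both the
# Fig.-4-style comparator model and the latency M-step of the mixture cure
# EM, where censored subjects enter risk sets with fractional weight.

# upper-triangle cross products x[,i]*x[,j], i <= j, as an n x p(p+1)/2 matrix
tri_cross <- function(x) {
  p <- ncol(x)
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  out <- x[, idx[, 1L], drop = FALSE] * x[, idx[, 2L], drop = FALSE]
  attr(out, "idx") <- idx
  out
}

tri_to_sym <- function(v, p) {
  m <- matrix(0, p, p)
  m[upper.tri(m, diag = TRUE)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# presort the data once; Newton iterations then cost O(n p^2) each
cox_prep <- function(time, event, x, w) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; w_s <- w[ord]
  x_s <- x[ord, , drop = FALSE]
  is_ev <- e_s == 1 & w_s > 0
  tev <- unique(t_s[is_ev])
  # first index of each tie group (risk set = all with time >= t)
  first <- which(!duplicated(t_s))
  pos <- first[match(tev, t_s[first])]
  # weighted event mass per unique event time
  grp <- match(t_s, tev)                       # NA where time not an event time
  Dful <- rowsum((w_s * e_s)[!is.na(grp)], grp[!is.na(grp)])
  D <- numeric(length(tev)); D[as.integer(rownames(Dful))] <- Dful
  list(t_s = t_s, e_s = e_s, w_s = w_s, x_s = x_s,
       xt = if (ncol(x)) tri_cross(x_s) else NULL,
       tev = tev, pos = pos, D = D,
       ev_wx = if (ncol(x)) colSums((w_s * e_s) * x_s) else numeric(0))
}

cox_eval <- function(pr, beta, gradient = TRUE) {
  p <- ncol(pr$x_s)
  eta <- if (p) drop(pr$x_s %*% beta) else rep(0, length(pr$t_s))
  we <- pr$w_s * exp(eta)
  S0 <- revcumsum(we)[pr$pos]
  ll <- sum(pr$w_s * pr$e_s * eta) - sum(pr$D * log(S0))
  if (!p || !gradient)
    return(list(loglik = ll, score = numeric(0), info = matrix(0, 0, 0),
                S0 = S0))
  S1 <- revcumsum(we * pr$x_s)[pr$pos, , drop = FALSE]
  M <- S1 / S0
  S2 <- revcumsum(we * pr$xt)[pr$pos, , drop = FALSE]
  score <- pr$ev_wx - colSums(pr$D * M)
  info <- tri_to_sym(colSums(pr$D * S2 / S0), p) - crossprod(M, pr$D * M)
  list(loglik = ll, score = score, info = (info + t(info)) / 2, S0 = S0)
}

#' Evaluate the weighted Breslow partial likelihood
#'
#' Log partial likelihood, score vector and expected information of the
#' weighted Cox model at a given coefficient value. With a single binary
#' covariate evaluated at `beta = 0`, the score equals the log-rank
#' observed-minus-expected and the information equals the log-rank
#' variance (the classical score-test identity).
#'
#' @param time,event,x,weights as in [cox_fit()].
#' @param beta coefficient vector at which to evaluate.
#' @return list with `loglik`, `score`, `info`.
#' @export
cox_partial <- function(time, event, x, weights = NULL, beta) {
  w <- check_sample(time, event, weights)
  x <- as.matrix(x)
  pr <- cox_prep(time, event, x, w)
  cox_eval(pr, beta)[c("loglik", "score", "info")]
}

#' Fit a weighted Cox proportional hazards model
#'
#' Newton-Raphson maximizer of the weighted partial likelihood with Breslow
#' tie handling and step-halving (the log partial likelihood is
#' nondecreasing across iterations). Weights multiply both event counts and
#' risk-set sums, so fractional subjects are supported; the fitted
#' coefficients are invariant to a common rescaling of all weights, and so
#' is the Breslow baseline (event mass and risk sums scale together).
#'
#' @param time follow-up times (years).
#' @param event 0/1 event indicators.
#' @param x covariate matrix (no intercept). May have zero columns, in
#'   which case only the baseline is estimated.
#' @param weights optional nonnegative per-subject weights.
#' @param init optional starting coefficients (default 0).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @param zero_tail if `TRUE` the returned baseline survival is 0 beyond
#'   the last event time (the mixture-cure latency constraint).
#' @return object of class `cure_cox`: `coef`, `vcov`, `loglik` (at
#'   optimum), `loglik_trace`, `baseline` ([step_surv] of the Breslow
#'   baseline survival with hazard increments), `n_events`, `converged`,
#'   `flags`.
#' @examples
#' d <- data.frame(t = c(2, 4, 1, 5, 3), e = c(1, 1, 0, 1, 1), x = c(1, 0, 1, 0, 1))
#' cox_fit(d$t, d$e, cbind(x = d$x))
#' @export
cox_fit <- function(time, event, x, weights = NULL, init = NULL,
                    tol = 1e-9, max_iter = 100L, zero_tail = FALSE) {
  w <- check_sample(time, event, weights)
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  p <- ncol(x)
  keep <- w > 0
  if (sum(event[keep]) < 1) stop("at least one positively weighted event is required")
  if (p) {
    rng <- apply(x[keep, , drop = FALSE], 2L, function(col) diff(range(col)))
    if (any(rng == 0))
      stop("constant covariate in risk set: ",
           paste(colnames(x)[rng == 0], collapse = ", "))
  }
  pr <- cox_prep(time[keep], event[keep], x[keep, , drop = FALSE], w[keep])

  beta <- if (p) (init %||% rep(0, p)) else numeric(0)
  flags <- character(0)
  trace <- numeric(0)
  converged <- TRUE
  if (p) {
    ev <- cox_eval(pr, beta)
    trace <- ev$loglik
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      info <- ev$info
      delta <- tryCatch(solve(info, ev$score), error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) {
        ridge <- diag(p) * (mean(diag(info)) * 1e-8 + 1e-10)
        delta <- tryCatch(solve(info + ridge, ev$score), error = function(e) NULL)
        if (is.null(delta)) { flags <- c(flags, "singular_information"); break }
      }
      step <- 1
      repeat {
        cand <- beta + step * delta
        ev_new <- cox_eval(pr, cand)
        if (is.finite(ev_new$loglik) && ev_new$loglik >= ev$loglik - 1e-12) break
        step <- step / 2
        if (step < 2^-40) { cand <- beta; ev_new <- ev; break }
      }
      dl <- ev_new$loglik - ev$loglik
      beta <- cand; ev <- ev_new
      trace <- c(trace, ev$loglik)
      if (abs(dl) < tol * (abs(ev$loglik) + 0.1)) { converged <- TRUE; break }
    }
    if (max(abs(beta)) > 15) {
      flags <- c(flags, "monotone_likelihood")
      beta <- pmin(pmax(beta, -15), 15)
      converged <- FALSE
      ev <- cox_eval(pr, beta)
    }
    names(beta) <- colnames(x)
    vcov <- tryCatch(solve(ev$info), error = function(e) matrix(NA_real_, p, p))
    dimnames(vcov) <- list(colnames(x), colnames(x))
  } else {
    ev <- cox_eval(pr, beta)
    trace <- ev$loglik
    vcov <- matrix(0, 0, 0)
  }
  dH <- pr$D / ev$S0
  H <- cumsum(dH)
  baseline <- step_surv(pr$tev, exp(-H), hazard = dH,
                        tail = if (zero_tail) "zero" else "plateau")
  structure(list(coef = beta, vcov = vcov, loglik = ev$loglik,
                 loglik_trace = trace, baseline = baseline,
                 n_events = sum(event[keep] == 1), n = sum(keep),
                 converged = converged, flags = flags),
            class = "cure_cox")
}

#' @export
print.cure_cox <- function(x, ...) {
  cat(sprintf("Weighted Cox PH fit: n = %d, events = %d, loglik = %.4f%s\n",
              x$n, x$n_events, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  if (length(x$coef)) {
    tab <- cbind(coef = x$coef, HR = exp(x$coef),
                 se = sqrt(diag(x$vcov)))
    print(round(tab, 4))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Predict survival from a Cox fit
#'
#' Baseline survival raised to `exp(x beta)` for one covariate row.
#'
#' @param fit a `cure_cox` object.
#' @param x_new covariate vector (or 1-row matrix) on the fitted scale.
#' @return a [step_surv].
#' @export
cox_survival <- function(fit, x_new) {
  stopifnot(inherits(fit, "cure_cox"))
  eta <- if (length(fit$coef)) sum(as.numeric(x_new) * fit$coef) else 0
  b <- fit$baseline
  step_surv(b$time, b$surv^exp(eta), tail = b$tail)
}
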