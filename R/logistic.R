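# Weighted logistic (Bernoulli) likelihood maximizer by Newton-Raphson with
# step-halving. Responses may be fractional in [0, 1] (posterior uncured
# weights in the EM incidence M-step) and subjects may carry nonnegative
# weights. Under separation the likelihood is monotone in some direction;
# a small ridge penalty (1e-4) is then used as a fallback and coefficients
# are capped, both flagged.

logit_loglik <- function(z, y, w, b) {
  eta <- drop(z %*% b)
  # numerically stable log-likelihood: y*eta - log(1+exp(eta))
  sum(w * (y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))))
}

#' Weighted logistic regression with fractional responses
#'
#' Newton-Raphson maximizer of the weighted Bernoulli log-likelihood
#' `sum w_i [y_i eta_i - log(1 + exp(eta_i))]` where `y` may be any value
#' in `[0, 1]`. Interior solutions are solved to score norm below `tol`.
#' If the information matrix is singular or the iteration diverges
#' (separation), the fit falls back to a ridge penalty of `1e-4` and the
#' result is flagged; coefficients are capped at `+/- cap`.
#'
#' @param z design matrix including the intercept column.
#' @param y responses in `[0, 1]` (may be fractional).
#' @param weights optional nonnegative subject weights.
#' @param start optional starting value (default 0). The returned
#'   unpenalized log-likelihood never falls below its value at `start`.
#' @param tol score-norm convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @param cap absolute bound on coefficients.
#' @param ridge ridge penalty used by the separation fallback.
#' @return list with `coef`, `loglik` (unpenalized), `score_norm`,
#'   `converged`, `flags`, `vcov`.
#' @export
logit_fit <- function(z, y, weights = NULL, start = NULL, tol = 1e-8,
                      max_iter = 100L, cap = 20, ridge = 1e-4) {
  z <- as.matrix(z)
  p <- ncol(z)
  n <- nrow(z)
  if (length(y) != n) stop("response length must match design rows")
  if (any(y < -1e-12 | y > 1 + 1e-12)) stop("responses must lie in [0, 1]")
  y <- pmin(pmax(y, 0), 1)
  w <- if (is.null(weights)) rep(1, n) else weights
  if (any(w < 0)) stop("weights must be nonnegative")
  b0 <- start %||% rep(0, p)
  ll0 <- logit_loglik(z, y, w, b0)

  run_newton <- function(b, pen) {
    obj <- function(b) logit_loglik(z, y, w, b) - pen / 2 * sum(b^2)
    f <- obj(b)
    converged <- FALSE
    flags <- character(0)
    for (it in seq_len(max_iter)) {
      eta <- drop(z %*% b)
      mu <- expit(eta)
      score <- drop(crossprod(z, w * (y - mu))) - pen * b
      if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
      info <- crossprod(z, (w * mu * (1 - mu)) * z) + pen * diag(p)
      delta <- tryCatch(solve(info, score), error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) {
        flags <- c(flags, "singular_information"); break
      }
      step <- 1
      repeat {
        cand <- b + step * delta
        f_new <- obj(cand)
        if (is.finite(f_new) && f_new >= f - 1e-12) break
        step <- step / 2
        if (step < 2^-40) { cand <- b; f_new <- f; break }
      }
      b <- cand; f <- f_new
      if (max(abs(b)) > cap * 2) { flags <- c(flags, "diverging"); break }
    }
    list(b = b, converged = converged, flags = flags)
  }

  fit <- run_newton(b0, 0)
  flags <- fit$flags
  if (!fit$converged) {
    # separation / singular information: ridge fallback from the start value
    warning("logistic fit did not reach an interior optimum; using ridge fallback",
            call. = FALSE)
    flags <- unique(c(flags, "ridge_fallback"))
    fit <- run_newton(b0, ridge)
  }
  b <- fit$b
  if (max(abs(b)) > cap) {
    flags <- unique(c(flags, "boundary"))
    b <- pmin(pmax(b, -cap), cap)
  }
  # monotone-ascent guard: never return a value below the start point
  if (logit_loglik(z, y, w, b) < ll0) {
    flags <- unique(c(flags, "kept_start"))
    b <- b0
  }
  eta <- drop(z %*% b)
  mu <- expit(eta)
  score <- drop(crossprod(z, w * (y - mu)))
  info <- crossprod(z, (w * mu * (1 - mu)) * z)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  names(b) <- colnames(z)
  list(coef = b, loglik = logit_loglik(z, y, w, b),
       score_norm = sqrt(sum(score^2)),
       converged = fit$converged, flags = flags, vcov = vcov)
}
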