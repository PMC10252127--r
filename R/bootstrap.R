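# Nonparametric case-resampling bootstrap for the mixture cure model, and
# stratified cure/latency summaries. The standard report quotes, for
# each coefficient, the point estimate with bootstrap SD and a two-sided
# Wald p-value, plus percentile CIs for cure probabilities and stratum
# medians; asymptotic information for the semiparametric EM is delicate,
# so the bootstrap is the default inference route.

#' Bootstrap inference for a mixture cure fit
#'
#' Case-resampling bootstrap: subjects are resampled with replacement and
#' the EM refitted per replicate. SEs are the SDs of replicate
#' coefficients, CIs are percentile intervals, and p-values are two-sided
#' Wald tests of the original estimate against the bootstrap SE.
#' Replicates that fail to converge (or are degenerate, e.g. no events)
#' are dropped and counted; more than 20% failures attaches a warning to
#' the result.
#'
#' @param fit a `curemix` object.
#' @param B number of bootstrap replicates (default 500; at least 50).
#' @param seed integer seed making the resampling reproducible.
#' @return object of class `curemix_boot`: replicate coefficient matrix
#'   `reps` (incidence then latency columns), baselines `S0`, `se`, `ci`
#'   (percentile, coefficient scale), `p`, `mean_cure` replicates,
#'   `n_failed`, `warning`.
#' @export
cure_bootstrap <- function(fit, B = 500L, seed = 1L) {
  stopifnot(inherits(fit, "curemix"), B >= 50L)
  set.seed(as.integer(seed))
  n <- fit$n
  est <- c(fit$b, fit$beta)
  k <- length(est)
  names(est) <- c(paste0("incidence.", names(fit$b)),
                  if (length(fit$beta)) paste0("latency.", names(fit$beta)))
  reps <- matrix(NA_real_, B, k, dimnames = list(NULL, names(est)))
  S0_list <- vector("list", B)
  mean_cure <- rep(NA_real_, B)
  idx_all <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  for (bb in seq_len(B)) {
    idx <- idx_all[bb, ]
    rep_fit <- tryCatch(
      suppressWarnings(curemix_fit(fit$time[idx], fit$event[idx],
                                   fit$z[idx, , drop = FALSE],
                                   fit$x[idx, , drop = FALSE],
                                   init = list(b = fit$b, beta = fit$beta),
                                   pi_fixed = fit$pi_fixed)),
      error = function(e) NULL)
    if (is.null(rep_fit) || !rep_fit$converged) next
    reps[bb, ] <- c(rep_fit$b, rep_fit$beta)
    S0_list[[bb]] <- rep_fit$S0
    # mean cure probability of the original cohort under the replicate fit
    mean_cure[bb] <- mean(1 - expit(drop(fit$z %*% rep_fit$b)))
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  warn <- NULL
  if (n_failed > 0.2 * B) {
    warn <- sprintf("%d of %d bootstrap replicates failed to converge", n_failed, B)
    warning(warn, call. = FALSE)
  }
  se <- apply(reps[ok, , drop = FALSE], 2L, stats::sd)
  ci <- t(apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE))
  p <- 2 * stats::pnorm(-abs(est / ifelse(se > 0, se, Inf)))
  p[se == 0] <- 1
  structure(list(reps = reps[ok, , drop = FALSE], S0 = S0_list[ok],
                 est = est, se = se, ci = ci, p = p,
                 mean_cure = mean_cure[ok],
                 mean_cure_ci = stats::quantile(mean_cure[ok],
                                                c(0.025, 0.975), na.rm = TRUE),
                 B = B, n_failed = n_failed, warning = warn, seed = seed),
            class = "curemix_boot")
}

#' @export
print.curemix_boot <- function(x, ...) {
  cat(sprintf("Mixture cure bootstrap: %d replicates kept (%d failed), seed %d\n",
              nrow(x$reps), x$n_failed, x$seed))
  tab <- cbind(estimate = x$est, SD = x$se, ci_lo = x$ci[, 1L],
               ci_hi = x$ci[, 2L], p = x$p)
  print(round(tab, 4))
  invisible(x)
}

stratum_stats <- function(b, beta, S0, z_rows, x_rows) {
  cure <- mean(1 - expit(drop(z_rows %*% b)))
  eta <- if (length(beta)) drop(x_rows %*% beta) else rep(0, nrow(z_rows))
  su_mean <- vapply(seq_along(S0$surv), function(k)
    mean(S0$surv[k]^exp(eta)), numeric(1))
  med <- median_from_curve(step_surv(S0$time, cummin(su_mean), tail = "zero"))
  c(cure = cure, median = as.numeric(med))
}

#' Stratified cure probability and median latency summary
#'
#' For each level of each stratifying variable: the number of subjects,
#' the mean predicted cure probability (x100%), and the median event time
#' of uncured subjects (median of the stratum's mean uncured survival
#' curve), with bootstrap percentile CIs when a [cure_bootstrap()] object
#' is supplied. Continuous stratifiers should be categorized (e.g. by
#' their medians) before calling. Empty strata are reported with `n = 0`
#' and no estimates; strata whose mean uncured curve never crosses 0.5
#' get an `NA` median (flagged, never silent).
#'
#' @param fit a `curemix` object (formula interface, so the data are
#'   stored).
#' @param strata character vector of column names in the fitted data (or
#'   `newdata`) to stratify by, each treated as a factor. Include `"all"`
#'   for the whole-cohort row.
#' @param boot optional `curemix_boot`.
#' @param newdata optional data frame overriding the fitted data.
#' @return data frame with one row per stratum level.
#' @export
strata_summary <- function(fit, strata = "all", boot = NULL, newdata = NULL) {
  data <- newdata %||% fit$data
  if (is.null(data)) stop("fit carries no data; refit via the formula interface")
  d <- new_designs(fit, data)
  rows <- list()
  for (v in strata) {
    levs <- if (v == "all") list(all = seq_len(nrow(data)))
    else {
      f <- data[[v]]
      if (!is.factor(f)) f <- factor(f)   # keep declared (possibly empty) levels
      split(seq_len(nrow(data)), f)
    }
    for (lev in names(levs)) {
      idx <- levs[[lev]]
      if (!length(idx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev, n = 0L, cure_pct = NA_real_,
          cure_lo = NA_real_, cure_hi = NA_real_, median_years = NA_real_,
          median_lo = NA_real_, median_hi = NA_real_)
        next
      }
      st <- stratum_stats(fit$b, fit$beta, fit$S0,
                          d$z[idx, , drop = FALSE], d$x[idx, , drop = FALSE])
      ci_c <- ci_m <- c(NA_real_, NA_real_)
      if (!is.null(boot) && nrow(boot$reps)) {
        bs <- vapply(seq_len(nrow(boot$reps)), function(r) {
          bb <- boot$reps[r, seq_along(fit$b)]
          be <- boot$reps[r, length(fit$b) + seq_along(fit$beta)]
          stratum_stats(bb, be, boot$S0[[r]],
                        d$z[idx, , drop = FALSE], d$x[idx, , drop = FALSE])
        }, numeric(2))
        ci_c <- stats::quantile(bs[1L, ], c(0.025, 0.975), na.rm = TRUE)
        ci_m <- stats::quantile(bs[2L, ], c(0.025, 0.975), na.rm = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, n = length(idx),
        cure_pct = 100 * st[["cure"]],
        cure_lo = 100 * ci_c[[1L]], cure_hi = 100 * ci_c[[2L]],
        median_years = st[["median"]],
        median_lo = ci_m[[1L]], median_hi = ci_m[[2L]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a mixture cure fit (and optional bootstrap) to JSON
#'
#' Writes a report with separate latency (HR) and incidence (OR) blocks,
#' convergence information, and — when a bootstrap is supplied — SD, 95%
#' CI and p-value columns. The baseline survival is written alongside as
#' a lossless CSV when `s0_csv` is given.
#'
#' @param fit a `curemix` object.
#' @param path output JSON path.
#' @param boot optional `curemix_boot`.
#' @param s0_csv optional path for the baseline survival CSV.
#' @return `path`, invisibly.
#' @export
write_curemix_json <- function(fit, path, boot = NULL, s0_csv = NULL) {
  s <- summary(fit, boot = boot)
  out <- list(
    incidence = cbind(term = rownames(s$incidence), s$incidence),
    latency = cbind(term = rownames(s$latency), s$latency),
    cure_probability_pct = 100 * s$cure_probability,
    median_uncured_years = s$median_uncured,
    converged = fit$converged, n_iter = fit$n_iter,
    loglik = fit$loglik, n = fit$n, n_events = fit$n_events)
  if (!is.null(boot)) {
    out$bootstrap <- list(B = boot$B, n_failed = boot$n_failed,
                          seed = boot$seed,
                          mean_cure_ci_pct = 100 * as.numeric(boot$mean_cure_ci))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(s0_csv)) write_step_surv_csv(fit$S0, s0_csv)
  invisible(path)
}
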