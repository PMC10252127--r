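# Cohort I/O, analysis-variable encoding, descriptive baseline table with
# group tests, and the end-to-end analysis: KM/log-rank by the clinical
# stratifiers, the cure-test profile, the mixture cure fit with bootstrap
# inference, stratified cure summaries, Cox-vs-cure individualized curve
# ensembles, and the propensity-matched age-stratified subgroup analysis.

patient_schema <- function() {
  list(required = c("patient_id", "time_years", "event_metastasis", "age",
                    "stage", "differentiation", "mean_dose",
                    "mean_dose_rate", "duration_days", "chemo",
                    "response_3m", "local_recurrence"),
       stage = c("early", "locally_advanced", "advanced"),
       differentiation = c("high", "low"),
       response_3m = c("CR", "PR", "SD", "PD"))
}

#' Load and validate a patient cohort CSV
#'
#' Schema-validated load of the pipeline patient table. Rows with missing
#' modelling columns, unknown category values or nonpositive follow-up
#' times are rejected and counted, each with its reason (exclusion
#' bookkeeping); more than 50% rejected is a hard error. A header-only
#' file yields an empty table with a warning.
#'
#' @param path CSV file with a header (schema: `patient_id`,
#'   `time_years`, `event_metastasis`, `age`, `stage`,
#'   `differentiation`, `mean_dose`, `mean_dose_rate`, `duration_days`,
#'   `chemo`, `response_3m`, `local_recurrence`).
#' @return the accepted rows, with attributes `rejected` (data frame of
#'   `patient_id`, `reason`) and `n_input`.
#' @export
load_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- patient_schema()
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(sc$required, names(raw))
  if (length(missing_cols))
    stop("input is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(raw)) {
    warning("input file has a header but no rows", call. = FALSE)
    out <- raw
    attr(out, "rejected") <- data.frame(patient_id = integer(0),
                                        reason = character(0))
    attr(out, "n_input") <- 0L
    return(out)
  }
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  num_cols <- c("time_years", "age", "mean_dose", "mean_dose_rate",
                "duration_days")
  for (v in c(num_cols, "event_metastasis", "chemo", "local_recurrence"))
    flag(is.na(suppressWarnings(as.numeric(raw[[v]]))), paste0("missing ", v))
  for (v in c("stage", "differentiation", "response_3m"))
    flag(is.na(raw[[v]]) | !(raw[[v]] %in% sc[[v]]),
         paste0("unknown ", v, " value"))
  flag(suppressWarnings(as.numeric(raw$time_years)) <= 0,
       "nonpositive follow-up time")
  flag(!(raw$event_metastasis %in% c(0, 1)), "event flag not 0/1")
  flag(!(raw$chemo %in% c(0, 1)), "chemo flag not 0/1")
  flag(!(raw$local_recurrence %in% c(0, 1)), "local recurrence flag not 0/1")
  bad <- !is.na(reason)
  if (mean(bad) > 0.5)
    stop("more than half of the rows were rejected (",
         sum(bad), " of ", nrow(raw), ")")
  out <- raw[!bad, , drop = FALSE]
  for (v in num_cols) out[[v]] <- as.numeric(out[[v]])
  out$stage <- factor(out$stage, levels = sc$stage)
  out$differentiation <- factor(out$differentiation,
                                levels = sc$differentiation)
  out$response_3m <- factor(out$response_3m, levels = sc$response_3m)
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(patient_id = raw$patient_id[bad],
                                      reason = reason[bad])
  attr(out, "n_input") <- nrow(raw)
  out
}

# permissive core of the encoding: derive whatever the available columns
# allow (used by the generator before outcomes exist)
add_derived_columns <- function(tab) {
  if (!is.null(tab$age)) {
    tab$age_gt53 <- as.integer(tab$age > 53)    # age 53 itself is "younger"
    tab$age_c <- tab$age - 53
  }
  if (!is.null(tab$stage))
    tab$stage_adv <- as.integer(tab$stage != "early")  # early = reference
  if (!is.null(tab$differentiation))
    tab$diff_low <- as.integer(tab$differentiation == "low")
  if (!is.null(tab$mean_dose))
    tab$dose_std <- as.numeric(scale(tab$mean_dose))
  if (!is.null(tab$mean_dose_rate)) {
    if (diff(range(tab$mean_dose_rate)) == 0)
      stop("all mean dose rates identical; the LARS/HARS median split is undefined")
    med <- stats::median(tab$mean_dose_rate)
    tab$lars <- as.integer(tab$mean_dose_rate <= med)  # <= median -> LARS
    tab$rate_std <- as.numeric(scale(tab$mean_dose_rate))
  }
  if (!is.null(tab$duration_days))
    tab$duration_std <- as.numeric(scale(tab$duration_days))
  if (!is.null(tab$response_3m)) {
    r <- as.character(tab$response_3m)
    tab$response_grp <- factor(ifelse(r %in% c("SD", "PD"), "PD_SD", r),
                               levels = c("CR", "PR", "PD_SD"))
  }
  tab
}

#' Encode analysis variables
#'
#' Adds the derived modelling columns to a validated patient table:
#' `age_gt53` (strictly greater than 53), `age_c` (years, centred at 53),
#' `stage_adv` (locally advanced/advanced vs early reference),
#' `diff_low`, `lars` (mean dose rate at or below the cohort median; the
#' median split is an error if all dose rates are identical),
#' standardized `dose_std`, `rate_std`, `duration_std`, and the collapsed
#' `response_grp` (CR / PR / PD_SD). Encodings are deterministic given
#' the table; the interaction `age_gt53:lars` is formed by model
#' formulas, not stored.
#'
#' @param table a patient table (see [load_cohort_csv()]).
#' @return the table with derived columns appended.
#' @export
encode_analysis_variables <- function(table) {
  sc <- patient_schema()
  missing_cols <- setdiff(sc$required, names(table))
  if (length(missing_cols))
    stop("table is missing columns: ", paste(missing_cols, collapse = ", "))
  add_derived_columns(table)
}

fisher_or_chisq <- function(tab, seed = 1L) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- if (sum(tab) <= 1000) stats::fisher.test(tab)$p.value
    else {
      set.seed(as.integer(seed))
      stats::fisher.test(tab, simulate.p.value = TRUE, B = 10000L)$p.value
    }
    list(p = p, test = "fisher", flag = "*")
  } else {
    list(p = suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
         test = "chisq", flag = "")
  }
}

#' Descriptive baseline table with group tests
#'
#' Table-1-style descriptives by group (default: metastatic recurrence
#' status). Continuous variables are summarized as median (IQR) and
#' compared with the Wilcoxon rank-sum test; categorical variables as
#' counts (%) compared with the chi-square test, switching to Fisher's
#' exact test (flagged `*`) when any expected cell count is below 5
#' (exact enumeration up to table total 1000, seeded Monte Carlo beyond).
#' With a single group, descriptives are reported and tests omitted.
#'
#' @param data patient table (encoded or raw).
#' @param group name of the grouping column (two levels for tests).
#' @param continuous,categorical variable names to summarize; defaults
#'   cover the pipeline schema.
#' @param seed seed for Monte-Carlo Fisher tests.
#' @return data frame with one row per variable level: counts and
#'   percentages (or median/IQR) per group, `p_value`, `test`, `flag`.
#' @export
baseline_table <- function(data, group = "event_metastasis",
                           continuous = c("age", "mean_dose",
                                          "mean_dose_rate", "duration_days"),
                           categorical = c("differentiation", "stage",
                                           "chemo", "response_grp",
                                           "local_recurrence"),
                           seed = 1L) {
  continuous <- intersect(continuous, names(data))
  categorical <- intersect(categorical, names(data))
  g <- factor(data[[group]])
  two <- nlevels(g) == 2L
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  for (v in continuous) {
    x <- data[[v]]
    qs <- vapply(split(x, g), function(u)
      stats::quantile(u, c(0.5, 0.25, 0.75)), numeric(3))
    p <- if (two) stats::wilcox.test(x ~ g, exact = FALSE)$p.value else NA_real_
    add(variable = v, level = "",
        summary_overall = sprintf("%.1f (%.1f, %.1f)",
                                  stats::median(x),
                                  stats::quantile(x, 0.25),
                                  stats::quantile(x, 0.75)),
        summary_g1 = sprintf("%.1f (%.1f, %.1f)", qs[1, 1], qs[2, 1], qs[3, 1]),
        summary_g2 = if (two) sprintf("%.1f (%.1f, %.1f)",
                                      qs[1, 2], qs[2, 2], qs[3, 2]) else "",
        p_value = p, test = if (two) "wilcoxon" else "", flag = "")
  }
  for (v in categorical) {
    f <- factor(data[[v]])
    tab <- table(f, g)
    res <- if (two) fisher_or_chisq(t(tab), seed = seed)
    else list(p = NA_real_, test = "", flag = "")
    for (l in levels(f)) {
      cnt <- table(f)[[l]]
      add(variable = v, level = l,
          summary_overall = sprintf("%d (%.1f%%)", cnt,
                                    100 * cnt / length(f)),
          summary_g1 = sprintf("%d (%.1f%%)", tab[l, 1],
                               100 * tab[l, 1] / sum(tab[, 1])),
          summary_g2 = if (two) sprintf("%d (%.1f%%)", tab[l, 2],
                                        100 * tab[l, 2] / sum(tab[, 2]))
          else "",
          p_value = res$p, test = res$test, flag = res$flag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

log_stage <- function(log_path, stage, seed, t0, extra = list()) {
  rec <- c(list(stage = stage, seed = seed,
                seconds = round(as.numeric(Sys.time()) - t0, 3)), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full metastatic-recurrence analysis
#'
#' End-to-end orchestration on an encoded cohort: (1) KM curves and
#' two-group log-rank tests for the clinical stratifiers (stage, 3rd
#' month response, local recurrence, and LARS/HARS within age strata);
#' (2) the cure-test profile over yearly horizons; (3) the mixture cure
#' fit with incidence `stage_adv + dose_std + chemo + age_gt53 + lars +
#' age_gt53:lars` and latency `age_c + stage_adv + dose_std + rate_std +
#' chemo`, with case-resampling bootstrap inference; (4) stratified cure
#' probability / median latency summaries; (5) Cox-vs-cure mean
#' individualized survival curves; (6) the propensity-matched age-
#' stratified subgroup analysis. Every stage draws its seed from the one
#' master seed; stage failures are recorded and the bundle marked
#' partial. All outputs are written under `out_dir` as CSV/JSON plus a
#' `run_log.jsonl`.
#'
#' @param data an encoded cohort data frame (see
#'   [encode_analysis_variables()]), or a path to a cohort CSV (loaded
#'   and encoded).
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed master seed.
#' @param B bootstrap replicates (passed to [cure_bootstrap()]).
#' @param taus,c0s cure-test grids.
#' @return invisible list (`ReportBundle`): `table1`, `km`, `logrank`,
#'   `cure_profile`, `fit`, `boot`, `table2` (coefficient summary),
#'   `table3` (strata summary), `curves` (mean cure-model and Cox
#'   curves), `psm`, `errors`, `complete`.
#' @export
run_full_analysis <- function(data, out_dir = NULL, seed = 1L, B = 500L,
                              taus = 1:8, c0s = c(0, 0.7, 0.8)) {
  t0 <- as.numeric(Sys.time())
  if (is.character(data)) data <- encode_analysis_variables(load_cohort_csv(data))
  seeds <- substream_seeds(seed, c("table", "curetest", "fit", "boot", "psm"))
  log_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "km_curves"), showWarnings = FALSE)
    log_path <- file.path(out_dir, "run_log.jsonl")
    if (file.exists(log_path)) file.remove(log_path)
  }
  errors <- list()
  bundle <- list()
  run_stage <- function(name, seed, expr) {
    res <- tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(log_path))
      log_stage(log_path, name, seed, t0,
                list(ok = is.null(errors[[name]])))
    res
  }

  time <- data$time_years
  event <- data$event_metastasis
  bundle$table1 <- run_stage("baseline_table", seeds[["table"]],
                             baseline_table(data, seed = seeds[["table"]]))

  strat <- list(stage_adv = data$stage_adv,
                response_cr = as.integer(data$response_grp == "CR"),
                local_recurrence = data$local_recurrence,
                lars_young = ifelse(data$age_gt53 == 0, data$lars, NA),
                lars_old = ifelse(data$age_gt53 == 1, data$lars, NA))
  bundle$km <- list(all = km_estimate(time, event))
  bundle$logrank <- list()
  for (s in names(strat)) {
    keep <- !is.na(strat[[s]])
    v <- strat[[s]][keep]
    if (length(unique(v)) == 2L) {
      a <- keep & strat[[s]] == unique(v)[1]
      b2 <- keep & strat[[s]] == unique(v)[2]
      bundle$km[[paste0(s, "_", unique(v)[1])]] <- km_estimate(time[a], event[a])
      bundle$km[[paste0(s, "_", unique(v)[2])]] <- km_estimate(time[b2], event[b2])
      bundle$logrank[[s]] <- logrank_test(time[a], event[a], time[b2], event[b2])
    }
  }

  bundle$cure_profile <- run_stage("cure_test_profile", seeds[["curetest"]],
                                   cure_test_profile(time, event,
                                                     taus = taus, c0s = c0s))

  if (sum(event) == 0) {
    errors$curemix <- "no events: mixture cure model skipped"
  } else {
    bundle$fit <- run_stage("curemix", seeds[["fit"]], suppressWarnings(
      curemix(cbind(time_years, event_metastasis) ~ age_c + stage_adv +
                dose_std + rate_std + chemo,
              cureform = ~ stage_adv + dose_std + chemo + age_gt53 + lars +
                age_gt53:lars,
              data = data)))
  }
  if (!is.null(bundle$fit)) {
    bundle$boot <- run_stage("bootstrap", seeds[["boot"]], suppressWarnings(
      cure_bootstrap(bundle$fit, B = B, seed = seeds[["boot"]])))
    bundle$table2 <- summary(bundle$fit, boot = bundle$boot)
    data$age_grp <- factor(ifelse(data$age_gt53 == 1, ">53", "<=53"),
                           levels = c("<=53", ">53"))
    data$ars <- factor(ifelse(data$lars == 1, "LARS", "HARS"),
                       levels = c("HARS", "LARS"))
    bundle$table3 <- run_stage("strata_summary", seeds[["boot"]],
      strata_summary(bundle$fit,
                     strata = c("all", "age_grp", "differentiation",
                                "stage_adv", "ars", "chemo", "response_grp",
                                "local_recurrence"),
                     boot = bundle$boot, newdata = data))
    cox <- run_stage("cox_comparator", seeds[["fit"]],
      cox_fit(time, event,
              as.matrix(data[c("age_c", "stage_adv", "dose_std",
                               "rate_std", "chemo")])))
    if (!is.null(cox)) {
      xmat <- as.matrix(data[c("age_c", "stage_adv", "dose_std",
                               "rate_std", "chemo")])
      eta <- drop(xmat %*% cox$coef)
      cb <- cox$baseline
      cox_mean <- vapply(seq_along(cb$surv), function(k)
        mean(cb$surv[k]^exp(eta)), numeric(1))
      bundle$curves <- list(
        cure_mean = marginal_mean_curve(bundle$fit),
        cox_mean = step_surv(cb$time, cummin(cox_mean)),
        cox = cox)
    }
    bundle$psm <- run_stage("psm_subgroups", seeds[["psm"]],
                            psm_subgroup_analysis(data))
  }

  bundle$errors <- errors
  bundle$complete <- length(errors) == 0L
  bundle$seed <- seed

  if (!is.null(out_dir)) {
    utils::write.csv(bundle$table1, file.path(out_dir, "table1.csv"),
                     row.names = FALSE)
    for (nm in names(bundle$km))
      write_step_surv_csv(bundle$km[[nm]],
                          file.path(out_dir, "km_curves",
                                    paste0(nm, ".csv")))
    if (!is.null(bundle$cure_profile))
      utils::write.csv(bundle$cure_profile,
                       file.path(out_dir, "cure_test_profile.csv"),
                       row.names = FALSE)
    if (!is.null(bundle$fit))
      write_curemix_json(bundle$fit, file.path(out_dir, "table2.json"),
                         boot = bundle$boot,
                         s0_csv = file.path(out_dir, "baseline_s0.csv"))
    if (!is.null(bundle$table3))
      utils::write.csv(bundle$table3, file.path(out_dir, "table3.csv"),
                       row.names = FALSE)
    if (!is.null(bundle$curves)) {
      d1 <- as.data.frame(bundle$curves$cure_mean)
      d1$model <- "mixture_cure"
      d2 <- as.data.frame(bundle$curves$cox_mean)
      d2$model <- "cox"
      utils::write.csv(rbind(d1, d2), file.path(out_dir, "curves_fig4.csv"),
                       row.names = FALSE)
    }
    if (!is.null(bundle$psm)) {
      psm_json <- lapply(bundle$psm, function(s) {
        if (!is.null(s$skipped)) return(list(n = s$n, skipped = s$skipped))
        list(n = s$n, n_pairs = nrow(s$pairs$pairs), or_lars = s$or_lars,
             hr_rate = s$hr_rate, cure_by_arm = as.list(s$cure_by_arm))
      })
      jsonlite::write_json(psm_json, file.path(out_dir, "table4.json"),
                           auto_unbox = TRUE, digits = NA)
      for (s in names(bundle$psm)) {
        if (is.null(bundle$psm[[s]]$skipped))
          utils::write.csv(bundle$psm[[s]]$pairs$pairs,
                           file.path(out_dir,
                                     paste0("matched_pairs_", s, ".csv")),
                           row.names = FALSE)
      }
    }
    if (!is.null(log_path))
      log_stage(log_path, "done", seed, t0,
                list(complete = bundle$complete,
                     n_errors = length(errors)))
  }
  invisible(bundle)
}
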