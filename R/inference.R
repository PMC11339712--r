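# Nonparametric bootstrap over patients and end-to-end orchestration.

#' Bootstrap plan
#'
#' @param n_resamples number of bootstrap resamples (default 500).
#' @param seed root seed; each resample uses an independently derived stream,
#'   so resamples are reproducible individually.
#' @param level confidence level in percent (default 95).
#' @return A `bootstrap_plan`.
#' @export
bootstrap_plan <- function(n_resamples = 500L, seed = 1L, level = 95) {
  if (n_resamples < 1) stop_config("n_resamples", "must be >= 1")
  if (level <= 0 || level >= 100) stop_config("level", "must be in (0, 100)")
  structure(list(n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), level = level),
            class = "bootstrap_plan")
}

#' Percentile confidence interval from bootstrap estimates
#'
#' Order-statistic (inverse empirical CDF) percentiles: the lower bound is
#' the `ceiling(alpha/2 * B)`-th order statistic and the upper bound the
#' `ceiling((1 - alpha/2) * B)`-th. A constant estimate vector yields a
#' zero-width interval, and endpoints are monotone in the level.
#'
#' @param x numeric vector of resample estimates.
#' @param level confidence level in percent.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(x, level = 95) {
  x <- x[!is.na(x)]
  a <- (1 - level / 100) / 2
  q <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 1)
  c(lower = q[1], upper = q[2])
}

#' Patient-level nonparametric bootstrap of an estimator
#'
#' Draws patients with replacement (sample size preserved), re-runs the full
#' estimator on each resample, and returns percentile confidence intervals.
#' Resampling is at the patient level, before any cloning, so the Trial 2
#' clones of one patient always travel together. Resamples where the
#' estimator fails (e.g. non-convergence) are excluded and counted; more
#' than 10% failures is an error.
#'
#' @param stat_fn function taking an integer index vector (row indices into
#'   the original cohort, with repeats) and returning a named numeric vector
#'   of estimates. Must succeed on the identity index.
#' @param n number of patients in the original cohort.
#' @param plan a [bootstrap_plan()].
#' @return list with `point` (estimates on the original sample), `ci`
#'   (matrix with `lower`/`upper` rows), `resamples` (matrix of resample
#'   estimates) and `n_failed`.
#' @export
bootstrap_estimates <- function(stat_fn, n, plan = bootstrap_plan()) {
  point <- stat_fn(seq_len(n))
  B <- plan$n_resamples
  ests <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(derive_seed(plan$seed, b),
                     sample.int(n, n, replace = TRUE))
    r <- tryCatch(stat_fn(idx), error = function(e) NULL)
    if (is.null(r)) {
      n_failed <- n_failed + 1L
    } else {
      ests[b, ] <- r
    }
  }
  if (n_failed > 0.1 * B) {
    stop(sprintf("%d of %d bootstrap resamples failed", n_failed, B),
         call. = FALSE)
  }
  if (n_failed > 0) {
    message(n_failed, " bootstrap resamples failed and were excluded")
  }
  ci <- vapply(seq_along(point), function(j) {
    percentile_ci(ests[, j], plan$level)
  }, numeric(2))
  colnames(ci) <- names(point)
  list(point = point, ci = ci, resamples = ests, n_failed = n_failed)
}

# Trial 1 estimator on a resample index: refit propensity and weights, then
# weighted and crude KM risks at the horizon.
trial1_stat_fn <- function(cohort, horizon = 730,
                           outcome = outcome_definition("composite"),
                           truncation_percentile = 99) {
  force(cohort); force(horizon); force(outcome); force(truncation_percentile)
  function(idx) {
    sub <- cohort[idx, , drop = FALSE]
    ps <- fit_propensity(sub)
    w <- truncate_weights(stabilized_weights(ps, sub$arm),
                          truncation_percentile)
    cw <- weighted_km(sub, w, outcome, horizon)
    cu <- weighted_km(sub, NULL, outcome, horizon)
    rt <- risk_at(cw$colchicine, horizon)
    rc <- risk_at(cw$NSAID, horizon)
    c(risk_treated = rt, risk_control = rc, rd = rt - rc,
      rr = if (rc > 0) rt / rc else NA_real_,
      rd_crude = risk_at(cu$colchicine, horizon) - risk_at(cu$NSAID, horizon))
  }
}

#' Bootstrap the Trial 1 weighted analysis
#'
#' @param cohort a `trial_cohort`.
#' @param plan a [bootstrap_plan()].
#' @param horizon horizon in days.
#' @param outcome an [outcome_definition()].
#' @param truncation_percentile weight truncation percentile.
#' @return See [bootstrap_estimates()].
#' @export
bootstrap_trial1 <- function(cohort, plan = bootstrap_plan(), horizon = 730,
                             outcome = outcome_definition("composite"),
                             truncation_percentile = 99) {
  bootstrap_estimates(trial1_stat_fn(cohort, horizon, outcome,
                                     truncation_percentile),
                      nrow(cohort), plan)
}

# Subset an adjudicated person-interval table to a patient resample,
# relabelling duplicated patients so clones never share an id.
resample_intervals <- function(base, row_idx_by_patient, idx) {
  rows <- unlist(row_idx_by_patient[idx], use.names = FALSE)
  reps <- lengths(row_idx_by_patient[idx])
  out <- base[rows, , drop = FALSE]
  out$id <- rep(seq_along(idx), reps)
  for (a in c("horizon", "interval_days", "grace_days")) {
    attr(out, a) <- attr(base, a)
  }
  class(out) <- class(base)
  out
}

#' Bootstrap the Trial 2 clone-censor-weight analysis
#'
#' Cloning and protocol adjudication are deterministic per patient, so the
#' adjudicated person-interval table is built once; each resample re-selects
#' patients (clones travelling together), refits the censoring models,
#' recomputes the cumulative weights and refits the outcome model.
#'
#' @inheritParams run_trial2
#' @param plan a [bootstrap_plan()].
#' @param outcome an [outcome_definition()].
#' @return See [bootstrap_estimates()].
#' @export
bootstrap_trial2 <- function(cohort, db, plan = bootstrap_plan(),
                             horizon = 720L, grace_days = 30L,
                             truncation_percentile = 99,
                             outcome = outcome_definition("composite")) {
  base <- adjudicate_protocol(
    clone_and_discretize(cohort, db, 30L, horizon, grace_days))
  row_idx <- split(seq_len(nrow(base)), match(base$id, cohort$id))
  row_idx <- row_idx[order(as.integer(names(row_idx)))]

  stat_fn <- function(idx) {
    sub <- cohort[idx, , drop = FALSE]
    sub$id <- seq_along(idx)
    tab <- resample_intervals(base, row_idx, idx)
    tab <- suppressMessages(fit_censoring_models(tab, sub))
    tab <- compute_tv_weights(tab, truncation_percentile)
    fit <- fit_outcome_model(tab, outcome)
    curves <- predict_risk_curves(fit, horizon)
    rt <- risk_at(curves$long_term, horizon)
    rc <- risk_at(curves$short_term, horizon)
    c(risk_treated = rt, risk_control = rc, rd = rt - rc,
      rr = if (rc > 0) rt / rc else NA_real_)
  }
  bootstrap_estimates(stat_fn, nrow(cohort), plan)
}

#' Run both emulated trials end to end
#'
#' From a generator configuration (or a pre-built claims database), builds
#' the cohort with attrition, fits the propensity model and stabilized
#' truncated weights, reports covariate balance, runs the Trial 1 weighted
#' Kaplan-Meier analysis and the Trial 2 clone-censor-weight analysis over
#' all outcomes, optionally bootstraps the composite effect estimates, and
#' (for synthetic inputs) attaches the counterfactual simulation truth.
#'
#' @param config a [dgp_config()] (a database is simulated) or a `claims_db`.
#' @param spec an [eligibility_spec()]; defaults to the config's study
#'   window when `config` is a `dgp_config`.
#' @param horizon Trial 1 horizon in days (730).
#' @param horizon_t2 Trial 2 horizon in days, multiple of 30 (720).
#' @param boot a [bootstrap_plan()] or NULL to skip confidence intervals.
#' @param subgroups subset of `c("all", "cad", "nocad")` for Trial 1.
#' @param oracle_n_mc Monte-Carlo size for the simulation truth; 0 skips the
#'   oracle (and it is skipped for non-synthetic inputs).
#' @param out_dir if non-NULL, the report bundle is written there via
#'   [write_report_bundle()].
#' @return An `emulation_run` list: cohort, attrition, balance, weights,
#'   trial 1 and trial 2 estimate tables (with CI columns when bootstrapped),
#'   composite risk curves, truth (if requested) and a manifest.
#' @export
run_emulation <- function(config, spec = NULL, horizon = 730,
                          horizon_t2 = 720L, boot = NULL,
                          subgroups = "all", oracle_n_mc = 0,
                          out_dir = NULL) {
  is_synth <- inherits(config, "dgp_config")
  if (is_synth) {
    db <- simulate_cohort(config)
    if (is.null(spec)) {
      spec <- eligibility_spec(config$study_start, config$admin_end)
    }
  } else {
    db <- config
    if (is.null(spec)) {
      stop("an eligibility_spec is required when passing a claims_db",
           call. = FALSE)
    }
  }
  cohort <- build_cohort(db, spec, horizon)
  ps <- fit_propensity(cohort)
  w <- truncate_weights(stabilized_weights(ps, cohort$arm), 99)
  bal <- balance_table(cohort, w)

  trial1 <- do.call(rbind, lapply(subgroups, function(sg) {
    run_trial1(cohort, w, horizon, sg)
  }))
  trial2 <- run_trial2(cohort, db, horizon_t2)

  ci_t1 <- ci_t2 <- NULL
  if (!is.null(boot)) {
    b1 <- bootstrap_trial1(cohort, plan = boot, horizon = horizon)
    b2 <- bootstrap_trial2(cohort, db, plan = boot, horizon = horizon_t2)
    ci_t1 <- b1
    ci_t2 <- b2
    add_ci <- function(est, bt, outcome_name, horizon_used) {
      row <- est$outcome == outcome_name
      if (!is.null(est$subgroup)) row <- row & est$subgroup == "all"
      if (!is.null(est$adjustment)) row <- row & est$adjustment == "weighted"
      for (q in c("risk_treated", "risk_control", "rd", "rr")) {
        est[[paste0(q, "_lo")]] <- NA_real_
        est[[paste0(q, "_hi")]] <- NA_real_
        est[[paste0(q, "_lo")]][row] <- bt$ci["lower", q]
        est[[paste0(q, "_hi")]][row] <- bt$ci["upper", q]
      }
      est
    }
    trial1 <- add_ci(trial1, b1, "composite", horizon)
    trial2$estimates <- add_ci(trial2$estimates, b2, "composite", horizon_t2)
  }

  truth <- NULL
  if (is_synth && oracle_n_mc > 0) {
    strategies <- c("initiate-colchicine", "initiate-NSAID",
                    "colchicine-indefinite", "colchicine-90-days-then-stop")
    truth <- lapply(strategies, function(s) {
      simulate_counterfactual_risks(config, s, n_mc = oracle_n_mc,
                                    seed = derive_seed(config$seed, 99L),
                                    horizon = horizon_t2)
    })
    names(truth) <- strategies
  }

  run <- list(
    cohort = cohort,
    attrition = attr(cohort, "attrition"),
    propensity = ps, weights = w, balance = bal,
    trial1 = trial1, trial2 = trial2$estimates,
    trial1_boot = ci_t1, trial2_boot = ci_t2,
    curves_t1 = weighted_km(cohort, w, outcome_definition("composite"),
                            horizon),
    curves_t2 = trial2$curves,
    truth = truth,
    manifest = list(
      package_version = as.character(utils::packageVersion("tteclaims")),
      synthetic = is_synth,
      seed = if (is_synth) config$seed else NA_integer_,
      n_patients = nrow(cohort),
      horizon_trial1 = horizon, horizon_trial2 = horizon_t2,
      bootstrap = if (is.null(boot)) NULL else unclass(boot)
    )
  )
  class(run) <- "emulation_run"
  if (!is.null(out_dir)) write_report_bundle(run, out_dir)
  run
}

#' @export
print.emulation_run <- function(x, ...) {
  cat("<emulation_run>\n")
  cat(sprintf("  cohort: %d patients\n", nrow(x$cohort)))
  comp1 <- x$trial1[x$trial1$outcome == "composite" &
                      x$trial1$adjustment == "weighted", ][1, ]
  comp2 <- x$trial2[x$trial2$outcome == "composite", ][1, ]
  cat(sprintf("  trial 1 (weighted): %.1f%% vs %.1f%%, RD %.1f%%\n",
              100 * comp1$risk_treated, 100 * comp1$risk_control,
              100 * comp1$rd))
  cat(sprintf("  trial 2 (CCW):      %.1f%% vs %.1f%%, RD %.1f%%\n",
              100 * comp2$risk_treated, 100 * comp2$risk_control,
              100 * comp2$rd))
  invisible(x)
}
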