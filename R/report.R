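# Publication-style rendering of estimate tables and the machine-readable
# bundle.
# Every displayed value is derived, at render time, from a stored
# full-precision value by half-away-from-zero rounding.

fmt_pct <- function(x) {
  ifelse(is.na(x), "-", sprintf("%.1f%%", round_half_up(100 * x, 1)))
}

fmt_rr <- function(x) {
  ifelse(is.na(x), "-", sprintf("%.2f", round_half_up(x, 2)))
}

fmt_ci <- function(lo, hi, fmt) {
  ifelse(is.na(lo) | is.na(hi), "",
         sprintf(" (%s, %s)", sub("%", "", fmt(lo)), sub("%", "", fmt(hi))))
}

#' Render an estimate table with the published rounding rules
#'
#' Risks and risk differences as percentages to one decimal, risk ratios to
#' two decimals, NNT/NNH as integers, confidence bounds appended as
#' `"(lo, hi)"` where present. Rounding is half away from zero.
#'
#' @param estimates an estimate data.frame from [run_trial1()] or
#'   [run_trial2()], optionally with `*_lo`/`*_hi` CI columns.
#' @return data.frame of display strings, one row per outcome x adjustment.
#' @export
format_estimates <- function(estimates) {
  e <- estimates
  has <- function(nm) !is.null(e[[nm]])
  ci_or <- function(nm) if (has(nm)) e[[nm]] else rep(NA_real_, nrow(e))
  data.frame(
    outcome = e$outcome_label,
    adjustment = e$adjustment,
    risk_treated = paste0(fmt_pct(e$risk_treated),
                          fmt_ci(ci_or("risk_treated_lo"),
                                 ci_or("risk_treated_hi"), fmt_pct)),
    risk_control = paste0(fmt_pct(e$risk_control),
                          fmt_ci(ci_or("risk_control_lo"),
                                 ci_or("risk_control_hi"), fmt_pct)),
    risk_difference = paste0(fmt_pct(e$rd),
                             fmt_ci(ci_or("rd_lo"), ci_or("rd_hi"), fmt_pct)),
    risk_ratio = paste0(fmt_rr(e$rr),
                        fmt_ci(ci_or("rr_lo"), ci_or("rr_hi"), fmt_rr)),
    nnt = ifelse(is.na(e$nnt_value), "undefined",
                 paste(e$nnt_label, e$nnt_value)),
    stringsAsFactors = FALSE
  )
}

#' Write the full report bundle of an emulation run
#'
#' Writes `cohort.csv`, `attrition.csv`, `balance.csv`, `weights.csv`,
#' `trial1_estimates.csv`, `trial2_estimates.csv`, formatted display tables,
#' `risk_curves.csv` and a `report.json` manifest/summary into `dir`.
#'
#' @param run an `emulation_run` from [run_emulation()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(x, nm) {
    utils::write.csv(x, file.path(dir, nm), row.names = FALSE)
  }
  wcsv(as.data.frame(run$cohort), "cohort.csv")
  wcsv(data.frame(criterion = names(run$attrition),
                  count = as.integer(run$attrition)), "attrition.csv")
  wcsv(as.data.frame(run$balance), "balance.csv")
  wcsv(data.frame(id = run$cohort$id, ps = run$weights$ps,
                  weight_raw = run$weights$weight_raw,
                  weight = run$weights$weight), "weights.csv")
  wcsv(run$trial1, "trial1_estimates.csv")
  wcsv(run$trial2, "trial2_estimates.csv")
  wcsv(format_estimates(run$trial1), "trial1_table.csv")
  wcsv(format_estimates(run$trial2), "trial2_table.csv")

  curves <- rbind(
    data.frame(trial = "trial1", arm = "colchicine",
               run$curves_t1$colchicine),
    data.frame(trial = "trial1", arm = "NSAID", run$curves_t1$NSAID),
    data.frame(trial = "trial2", arm = "long_term",
               run$curves_t2$long_term),
    data.frame(trial = "trial2", arm = "short_term",
               run$curves_t2$short_term)
  )
  wcsv(curves, "risk_curves.csv")

  if (!is.null(run$truth)) {
    tr <- do.call(rbind, lapply(run$truth, function(t) {
      data.frame(strategy = t$strategy, horizon = t$horizon,
                 outcome = names(t$true_risk),
                 true_risk = as.numeric(t$true_risk),
                 mc_se = as.numeric(t$mc_se))
    }))
    wcsv(tr, "simulation_truth.csv")
  }

  if (requireNamespace("jsonlite", quietly = TRUE)) {
    comp1 <- run$trial1[run$trial1$outcome == "composite" &
                          run$trial1$adjustment == "weighted", ][1, ]
    comp2 <- run$trial2[run$trial2$outcome == "composite", ][1, ]
    summary <- list(
      manifest = run$manifest,
      attrition = as.list(run$attrition),
      trial1_composite = as.list(comp1),
      trial2_composite = as.list(comp2)
    )
    jsonlite::write_json(summary, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
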