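# Trial 1: weighted Kaplan-Meier risk curves and effect measures.

#' Outcome definitions for the emulated trials
#'
#' The primary composite (MALE, MACE, or death) and the five secondary
#' outcomes. For the MALE-only and MACE-only outcomes the competing risk of
#' death is handled with the non-censoring convention: the dead remain in the
#' risk set contributing weight but no events, so the curve estimates the
#' total-effect cumulative incidence in the presence of death.
#'
#' @param name one of `composite`, `male_death`, `mace_death`, `death`,
#'   `male`, `mace`.
#' @return An `outcome_definition` with `components` (subset of
#'   `mace`, `male`, `death`) and `death_is_competing`.
#' @export
outcome_definition <- function(name = c("composite", "male_death",
                                        "mace_death", "death", "male",
                                        "mace")) {
  name <- match.arg(name)
  components <- switch(name,
    composite = c("mace", "male", "death"),
    male_death = c("male", "death"),
    mace_death = c("mace", "death"),
    death = "death",
    male = "male",
    mace = "mace"
  )
  structure(
    list(name = name, components = components,
         death_is_competing = !"death" %in% components,
         label = switch(name,
           composite = "MALE, MACE, or death", male_death = "MALE or death",
           mace_death = "MACE or death", death = "Death", male = "MALE",
           mace = "MACE")),
    class = "outcome_definition"
  )
}

#' @rdname outcome_definition
#' @export
outcome_definitions <- function() {
  nms <- c("composite", "male_death", "mace_death", "death", "male", "mace")
  stats::setNames(lapply(nms, outcome_definition), nms)
}

# Per-patient (time, status) for an outcome, in days since index.
# Censoring candidates: disenrollment, administrative end, horizon. Under the
# competing-death convention a death occurring before censoring keeps the
# patient in the risk set (no event) through the horizon.
event_times <- function(cohort, outcome, horizon) {
  idx <- cohort$index_day
  day_of <- function(col) {
    d <- cohort[[col]] - idx
    ifelse(is.na(cohort[[col]]), Inf, d)
  }
  comp <- vapply(outcome$components, function(cp) {
    day_of(paste0(cp, "_day"))
  }, numeric(nrow(cohort)))
  t_event <- do.call(pmin, as.data.frame(comp))
  t_cens <- pmin(day_of("disenroll_day"), cohort$admin_end_day - idx, horizon)
  if (outcome$death_is_competing) {
    t_death <- day_of("death_day")
    t_cens <- ifelse(is.finite(t_death) & t_death <= t_cens, horizon, t_cens)
  }
  status <- as.integer(t_event <= t_cens)  # same-day ties: event wins
  time <- pmin(t_event, t_cens)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("invalid follow-up time (missing or non-positive)", call. = FALSE)
  }
  data.frame(time = time, status = status)
}

# Weighted product-limit estimator on (time, status, w); returns the full
# step curve as (day, risk). Events precede censorings on tied days.
km_curve <- function(time, status, w, horizon) {
  if (any(w < 0)) stop("negative weight", call. = FALSE)
  if (anyNA(time) || anyNA(w)) stop("missing time or weight", call. = FALSE)
  if (!length(time)) {
    curve <- data.frame(day = 0, risk = 0)
    class(curve) <- c("risk_curve", "data.frame")
    return(curve)
  }
  agg <- rowsum(cbind(w, w * status), group = time)
  times_u <- as.numeric(rownames(agg))
  w_leave <- agg[, 1]
  w_event <- agg[, 2]
  at_risk <- sum(w) - c(0, cumsum(w_leave))[seq_along(times_u)]
  is_ev <- w_event > 0
  frac <- ifelse(is_ev & at_risk > 0, 1 - w_event / at_risk, 1)
  surv <- cumprod(frac)
  curve <- data.frame(day = c(0, times_u[is_ev]),
                      risk = c(0, 1 - surv[is_ev]))
  curve <- curve[curve$day <= horizon, , drop = FALSE]
  rownames(curve) <- NULL
  class(curve) <- c("risk_curve", "data.frame")
  curve
}

#' Read a risk curve at a day (right-continuous step convention)
#'
#' @param curve a `risk_curve` (data.frame with `day`, `risk`).
#' @param day day at which to read the cumulative risk.
#' @return The last curve value at or before `day`.
#' @export
risk_at <- function(curve, day) {
  i <- findInterval(day, curve$day)
  if (i < 1) return(0)
  curve$risk[i]
}

#' Weighted Kaplan-Meier risk curves per arm
#'
#' Weighted product-limit estimator of cumulative risk (1 - survival) for one
#' outcome, per arm. Censoring events are disenrollment, administrative study
#' end and the horizon; with `death_is_competing` outcomes, deaths keep their
#' weight in the risk set without contributing events (total-effect
#' cumulative incidence). Same-day events precede censorings.
#'
#' @param cohort a `trial_cohort` with follow-up columns.
#' @param weights a `weight_set`, numeric vector, or NULL for unit weights.
#' @param outcome an [outcome_definition()].
#' @param horizon horizon in days.
#' @return Named list of `risk_curve`s, one per arm.
#' @export
weighted_km <- function(cohort, weights = NULL,
                        outcome = outcome_definition("composite"),
                        horizon = 730) {
  w <- if (is.null(weights)) {
    rep(1, nrow(cohort))
  } else if (inherits(weights, "weight_set")) {
    weights$weight
  } else {
    weights
  }
  ts <- event_times(cohort, outcome, horizon)
  arms <- c("colchicine", "NSAID")
  out <- lapply(arms, function(a) {
    m <- cohort$arm == a
    km_curve(ts$time[m], ts$status[m], w[m], horizon)
  })
  stats::setNames(out, arms)
}

#' NNT / NNH from a risk difference
#'
#' The rounded (half away from zero) inverse of the absolute risk difference,
#' labelled NNT for negative risk differences (treatment reduces risk) and
#' NNH for positive ones. A zero risk difference is flagged undefined.
#'
#' @param rd risk difference (treated minus control) on the probability
#'   scale.
#' @return list with `value` (integer or NA) and `label`
#'   (`"NNT"`, `"NNH"` or `"undefined"`).
#' @export
#' @examples
#' nnt_from_rd(-0.017)  # NNT 59
#' nnt_from_rd(0.054)   # NNH 19
nnt_from_rd <- function(rd) {
  if (is.na(rd) || rd == 0) {
    return(list(value = NA_real_, label = "undefined"))
  }
  list(value = round_half_up(1 / abs(rd)),
       label = if (rd < 0) "NNT" else "NNH")
}

#' Effect measures from per-arm risks
#'
#' Risk difference, risk ratio and NNT/NNH at a horizon, with the display
#' roundings used in the published tables (risks and risk differences to 0.1
#' percentage point, risk ratios to 2 decimals, NNT/NNH to the nearest
#' integer, all half away from zero). Undefined quantities (zero risk
#' difference, zero control risk) are flagged, not thrown.
#'
#' @param risk_treated,risk_control risks in `[0, 1]`.
#' @param horizon horizon in days (carried through for reporting).
#' @return An `effect_estimate` list.
#' @export
#' @examples
#' e <- effect_measures(0.299, 0.315, 730)
#' e$rr_display  # 0.95
effect_measures <- function(risk_treated, risk_control, horizon = 730) {
  stopifnot(risk_treated >= 0, risk_treated <= 1,
            risk_control >= 0, risk_control <= 1)
  rd <- risk_treated - risk_control
  rr <- if (risk_control > 0) risk_treated / risk_control else NA_real_
  nnt <- nnt_from_rd(rd)
  structure(
    list(horizon = horizon,
         risk_treated = risk_treated, risk_control = risk_control,
         rd = rd, rr = rr,
         nnt_value = nnt$value, nnt_label = nnt$label,
         risk_treated_display = round_half_up(100 * risk_treated, 1),
         risk_control_display = round_half_up(100 * risk_control, 1),
         rd_display = round_half_up(100 * rd, 1),
         rr_display = round_half_up(rr, 2),
         rr_undefined = risk_control == 0),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> horizon %d days\n", as.integer(x$horizon)))
  cat(sprintf("  risks: %.1f%% vs %.1f%%  RD %.1f%%  RR %s  %s %s\n",
              x$risk_treated_display, x$risk_control_display, x$rd_display,
              format(x$rr_display), x$nnt_label,
              ifelse(is.na(x$nnt_value), "-", format(x$nnt_value))))
  invisible(x)
}

#' Run the Trial 1 analysis over all outcomes
#'
#' Unadjusted (unit-weight) and IP-weighted Kaplan-Meier risks and effect
#' measures at the horizon for the composite and all secondary outcomes,
#' optionally in the coronary-artery-disease subgroups.
#'
#' @param cohort a `trial_cohort`.
#' @param weights a `weight_set` aligned to `cohort`.
#' @param horizon horizon in days (default 730).
#' @param subgroup `all`, `cad` or `nocad`.
#' @return data.frame with one row per outcome x adjustment, carrying risks,
#'   RD, RR and NNT/NNH.
#' @export
run_trial1 <- function(cohort, weights, horizon = 730, subgroup = "all") {
  subgroup <- match.arg(subgroup, c("all", "cad", "nocad"))
  keep <- switch(subgroup, all = rep(TRUE, nrow(cohort)),
                 cad = cohort$cad == 1, nocad = cohort$cad == 0)
  if (!any(keep)) stop("empty subgroup: ", subgroup, call. = FALSE)
  sub <- cohort[keep, , drop = FALSE]
  if (min(table(factor(sub$arm, c("colchicine", "NSAID")))) == 0) {
    stop("subgroup has an empty arm", call. = FALSE)
  }
  w <- if (inherits(weights, "weight_set")) weights$weight else weights
  w <- w[keep]

  rows <- list()
  for (od in outcome_definitions()) {
    for (adj in c("unadjusted", "weighted")) {
      wa <- if (adj == "unadjusted") rep(1, nrow(sub)) else w
      curves <- weighted_km(sub, wa, od, horizon)
      em <- effect_measures(risk_at(curves$colchicine, horizon),
                            risk_at(curves$NSAID, horizon), horizon)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = od$name, outcome_label = od$label, adjustment = adj,
        subgroup = subgroup,
        risk_treated = em$risk_treated, risk_control = em$risk_control,
        rd = em$rd, rr = em$rr,
        nnt_value = em$nnt_value, nnt_label = em$nnt_label,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "horizon") <- horizon
  out
}
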