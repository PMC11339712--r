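# Cohort construction: new-user identification, eligibility, baseline
# covariates over a 6-month lookback, and follow-up ascertainment.

#' Eligibility specification for the emulated trials
#'
#' @param start_day first day of the study window (trial enrolment opens).
#' @param admin_end administrative study close (last day of the window and of
#'   follow-up).
#' @param min_age_years minimum age, exclusive (default 66: age must exceed
#'   66 years at the index date).
#' @param lookback_days washout/lookback length (default 183 days for the
#'   6-month window).
#' @param pairing_window_days maximum gap between urate-lowering-therapy
#'   initiation and the prophylaxis (colchicine/NSAID) dispensing that
#'   defines the arm.
#' @return An `eligibility_spec` object.
#' @export
eligibility_spec <- function(start_day, admin_end, min_age_years = 66,
                             lookback_days = 183L, pairing_window_days = 14L) {
  if (lookback_days <= 0) stop_config("lookback_days", "must be positive")
  if (pairing_window_days < 0) stop_config("pairing_window_days", "must be >= 0")
  structure(
    list(start_day = start_day, admin_end = admin_end,
         min_age_years = min_age_years,
         lookback_days = as.integer(lookback_days),
         pairing_window_days = as.integer(pairing_window_days),
         washout_classes = c("ULT_allopurinol", "ULT_febuxostat",
                             "colchicine", "NSAID"),
         required_dx = c("PAD", "gout"),
         exclusion_dx = c("CKD4-5/ESKD", "hepatic_failure")),
    class = "eligibility_spec"
  )
}

# For each candidate row, is there an event with day in
# [index + lo_off, index + hi_off]?
any_in_window <- function(events, cand, lo_off, hi_off) {
  if (!nrow(events)) return(rep(FALSE, nrow(cand)))
  ev <- events[events$id %in% cand$id, , drop = FALSE]
  idx <- cand$index_day[match(ev$id, cand$id)]
  keep <- ev$day >= idx + lo_off & ev$day <= idx + hi_off
  cand$id %in% ev$id[keep]
}

count_in_window <- function(events, cand, lo_off, hi_off) {
  out <- rep(0L, nrow(cand))
  if (!nrow(events)) return(out)
  ev <- events[events$id %in% cand$id, , drop = FALSE]
  idx <- cand$index_day[match(ev$id, cand$id)]
  ev <- ev[ev$day >= idx + lo_off & ev$day <= idx + hi_off, , drop = FALSE]
  if (!nrow(ev)) return(out)
  tab <- table(ev$id)
  hit <- match(names(tab), as.character(cand$id))
  out[hit] <- as.integer(tab)
  out
}

# First event day strictly after index (NA if none).
first_after_index <- function(events, cand) {
  out <- rep(NA_real_, nrow(cand))
  if (!nrow(events)) return(out)
  ev <- events[events$id %in% cand$id, , drop = FALSE]
  idx <- cand$index_day[match(ev$id, cand$id)]
  ev <- ev[ev$day > idx, , drop = FALSE]
  if (!nrow(ev)) return(out)
  ev <- ev[order(ev$id, ev$day), ]
  ev <- ev[!duplicated(ev$id), ]
  out[match(ev$id, cand$id)] <- ev$day
  out
}

#' Identify new users of urate-lowering therapy and their prophylaxis arm
#'
#' A candidate is the first urate-lowering-therapy (ULT) dispensing for a
#' patient with no ULT, colchicine or NSAID dispensing in the prior
#' `lookback_days`, together with a colchicine or NSAID dispensing within the
#' pairing window starting at the ULT day. Patients with both prophylaxis
#' classes dispensed in the window are excluded (ambiguous arm).
#'
#' @param db a `claims_db`.
#' @param spec an [eligibility_spec()].
#' @return data.frame with columns `id`, `index_day`, `arm`, `ult_class`.
#' @export
find_initiators <- function(db, spec) {
  d <- db$dispensings
  ult <- d[d$drug_class %in% c("ULT_allopurinol", "ULT_febuxostat"), ,
           drop = FALSE]
  if (!nrow(ult)) {
    return(data.frame(id = integer(), index_day = numeric(),
                      arm = character(), ult_class = character()))
  }
  ult <- ult[order(ult$id, ult$day), ]
  first <- ult[!duplicated(ult$id), c("id", "day", "drug_class")]
  names(first) <- c("id", "index_day", "ult_class")

  rel <- d[d$drug_class %in% spec$washout_classes, , drop = FALSE]
  washout_viol <- any_in_window(rel, first, -spec$lookback_days, -1)
  first <- first[!washout_viol, , drop = FALSE]

  pro <- d[d$drug_class %in% c("colchicine", "NSAID"), , drop = FALSE]
  has_colch <- any_in_window(pro[pro$drug_class == "colchicine", , drop = FALSE],
                             first, 0, spec$pairing_window_days)
  has_nsaid <- any_in_window(pro[pro$drug_class == "NSAID", , drop = FALSE],
                             first, 0, spec$pairing_window_days)
  keep <- xor(has_colch, has_nsaid)
  out <- first[keep, , drop = FALSE]
  out$arm <- ifelse(has_colch[keep], "colchicine", "NSAID")
  rownames(out) <- NULL
  out[, c("id", "index_day", "arm", "ult_class")]
}

#' Apply trial eligibility criteria with first-failure attrition
#'
#' Retains candidates with: index inside the study window; continuous
#' enrollment covering the lookback through the index; at least one
#' health-system encounter (any diagnosis record) in the lookback; age above
#' the minimum at index; PAD and gout diagnoses on or before the index; and
#' no exclusion diagnosis (advanced CKD, hepatic failure) in the lookback.
#' Each dropped candidate is attributed to the first failing criterion.
#'
#' @param db a `claims_db`.
#' @param candidates output of [find_initiators()].
#' @param spec an [eligibility_spec()].
#' @return The eligible candidate rows with an `attrition` attribute: a named
#'   integer vector of per-criterion drop counts plus `candidates` and
#'   `eligible` totals.
#' @export
apply_eligibility <- function(db, candidates, spec) {
  cand <- candidates
  lb <- spec$lookback_days
  dx <- db$diagnoses

  birth <- db$patients$birth_date[match(cand$id, db$patients$id)]
  age <- (cand$index_day - birth) / 365.25

  en <- db$enrollment
  en_ok <- rep(FALSE, nrow(cand))
  if (nrow(en)) {
    ev <- en[en$id %in% cand$id, , drop = FALSE]
    idx <- cand$index_day[match(ev$id, cand$id)]
    cover <- ev$start_day <= idx - lb & ev$end_day >= idx
    en_ok <- cand$id %in% ev$id[cover]
  }

  checks <- list(
    study_window = cand$index_day >= spec$start_day &
      cand$index_day <= spec$admin_end,
    enrollment = en_ok,
    health_system_use = any_in_window(dx, cand, -lb, 0),
    age = age > spec$min_age_years,
    required_dx = Reduce(`&`, lapply(spec$required_dx, function(ct) {
      any_in_window(dx[dx$category == ct, , drop = FALSE], cand, -Inf, 0)
    })),
    exclusion_dx = !any_in_window(
      dx[dx$category %in% spec$exclusion_dx, , drop = FALSE], cand, -lb, 0)
  )

  fail_at <- rep(0L, nrow(cand))
  for (i in seq_along(checks)) {
    fail_at[fail_at == 0L & !checks[[i]]] <- i
  }
  attrition <- vapply(seq_along(checks), function(i) sum(fail_at == i),
                      integer(1))
  names(attrition) <- names(checks)

  out <- cand[fail_at == 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- c(candidates = nrow(cand), attrition,
                              eligible = nrow(out))
  out
}

#' Assemble baseline covariates over the lookback window
#'
#' Diagnosis and medication covariates use the `[index - lookback, index]`
#' window; age, sex, race, the carried Elixhauser score, calendar time and
#' enrolment time use the full record. No post-index information is used.
#'
#' @param db a `claims_db`.
#' @param cohort eligible candidate rows (`id`, `index_day`, `arm`, ...).
#' @param spec an [eligibility_spec()] (provides the lookback and the study
#'   window origin for calendar time).
#' @return `cohort` with one column per entry of [trial_covariates()].
#' @export
assemble_covariates <- function(db, cohort, spec) {
  if (!all(cohort$id %in% db$patients$id)) {
    stop("cohort contains ids absent from the claims database", call. = FALSE)
  }
  lb <- spec$lookback_days
  out <- cohort
  pt <- db$patients[match(cohort$id, db$patients$id), ]
  out$age <- (cohort$index_day - pt$birth_date) / 365.25
  out$sex_male <- as.integer(pt$sex == "M")
  out$race_nonwhite <- as.integer(pt$race == "non-white")
  out$elixhauser <- pt$elixhauser

  dx <- db$diagnoses
  dx_map <- c(obesity = "obesity", cad = "CAD", cerebrovascular = "cerebrovascular",
              heart_failure = "HF", afib = "AF", ckd13 = "CKD1-3",
              copd = "COPD", diabetes = "diabetes",
              rest_pain = "rest_pain", tissue_loss = "tissue_loss")
  for (nm in names(dx_map)) {
    out[[nm]] <- as.integer(any_in_window(
      dx[dx$category == dx_map[[nm]], , drop = FALSE], cohort, -lb, 0))
  }

  dd <- db$dispensings
  med_map <- c(insulin = "insulin", beta_blocker = "beta_blocker",
               statin = "statin", antiplatelet = "antiplatelet",
               cilostazol = "cilostazol", anticoagulation = "anticoagulant",
               prior_steroid = "steroid")
  for (nm in names(med_map)) {
    out[[nm]] <- as.integer(any_in_window(
      dd[dd$drug_class == med_map[[nm]], , drop = FALSE], cohort, -lb, 0))
  }
  out$antihtn_count <- Reduce(`+`, lapply(1:3, function(j) {
    as.integer(any_in_window(dd[dd$drug_class ==
                                  paste0("antihypertensive_", j), ,
                                drop = FALSE], cohort, -lb, 0))
  }))

  oc <- db$outcomes
  out$prior_mace <- as.integer(any_in_window(
    oc[oc$type == "MACE", , drop = FALSE], cohort, -lb, 0))
  out$prior_male <- as.integer(any_in_window(
    oc[oc$type == "MALE", , drop = FALSE], cohort, -lb, 0))

  out$gout_encounters <- count_in_window(
    dx[dx$category == "gout", , drop = FALSE], cohort, -lb, 0)

  out$calendar_time <- (cohort$index_day - spec$start_day) %/% 30L

  en <- db$enrollment
  ev <- en[en$id %in% cohort$id, , drop = FALSE]
  idx <- cohort$index_day[match(ev$id, cohort$id)]
  cover <- ev$start_day <= idx & ev$end_day >= idx
  ev <- ev[cover, , drop = FALSE]
  start <- ev$start_day[match(cohort$id, ev$id)]
  out$enrolment_time <- (cohort$index_day - start) %/% 30L

  out$febuxostat <- as.integer(cohort$ult_class == "ULT_febuxostat")
  out
}

#' Ascertain follow-up events and censoring times
#'
#' Records the first post-index MACE and MALE days, the death day, the
#' disenrollment day (end of the enrollment span covering the index, when it
#' closes before administrative end) and the administrative end day. The
#' composite event time is the minimum of the three event types; component
#' analyses carry the death day separately so estimators can apply the
#' non-censoring competing-death convention.
#'
#' @param db a `claims_db`.
#' @param cohort cohort rows with covariates.
#' @param spec an [eligibility_spec()] (provides `admin_end`).
#' @param horizon_days follow-up horizon in days (default 730).
#' @return A `trial_cohort` data.frame: `cohort` plus follow-up columns
#'   `mace_day`, `male_day`, `death_day`, `disenroll_day`, `admin_end_day`
#'   and a `horizon_days` attribute.
#' @export
ascertain_outcomes <- function(db, cohort, spec, horizon_days = 730L) {
  if (horizon_days <= 0) stop_config("horizon_days", "must be positive")
  oc <- db$outcomes
  out <- cohort
  out$mace_day <- first_after_index(oc[oc$type == "MACE", , drop = FALSE], cohort)
  out$male_day <- first_after_index(oc[oc$type == "MALE", , drop = FALSE], cohort)
  dth <- db$deaths
  dday <- dth$day[match(cohort$id, dth$id)]
  dday[!is.na(dday) & dday <= cohort$index_day] <- NA_real_
  out$death_day <- dday

  en <- db$enrollment
  ev <- en[en$id %in% cohort$id, , drop = FALSE]
  idx <- cohort$index_day[match(ev$id, cohort$id)]
  cover <- ev$start_day <= idx & ev$end_day >= idx
  ev <- ev[cover, , drop = FALSE]
  end <- ev$end_day[match(cohort$id, ev$id)]
  out$disenroll_day <- ifelse(end < spec$admin_end, end, NA_real_)
  out$admin_end_day <- spec$admin_end
  attr(out, "horizon_days") <- as.integer(horizon_days)
  attr(out, "attrition") <- attr(cohort, "attrition")
  class(out) <- c("trial_cohort", "data.frame")
  out
}

#' Build the full trial cohort from a claims database
#'
#' Convenience wrapper chaining [find_initiators()], [apply_eligibility()],
#' [assemble_covariates()] and [ascertain_outcomes()].
#'
#' @inheritParams ascertain_outcomes
#' @param spec an [eligibility_spec()].
#' @return A `trial_cohort` with an `attrition` attribute.
#' @export
#' @examples
#' cfg <- dgp_config(n_patients = 200, seed = 3)
#' db <- simulate_cohort(cfg)
#' spec <- eligibility_spec(cfg$study_start, cfg$admin_end)
#' cohort <- build_cohort(db, spec)
#' table(cohort$arm)
build_cohort <- function(db, spec, horizon_days = 730L) {
  cand <- find_initiators(db, spec)
  elig <- apply_eligibility(db, cand, spec)
  cov <- assemble_covariates(db, elig, spec)
  attr(cov, "attrition") <- attr(elig, "attrition")
  ascertain_outcomes(db, cov, spec, horizon_days)
}

#' @export
print.trial_cohort <- function(x, ...) {
  cat(sprintf("<trial_cohort> %d patients (%d colchicine, %d NSAID)\n",
              nrow(x), sum(x$arm == "colchicine"), sum(x$arm == "NSAID")))
  at <- attr(x, "attrition")
  if (!is.null(at)) {
    cat("  attrition:", paste(names(at), at, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
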