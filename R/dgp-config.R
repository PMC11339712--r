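#' Configuration for the synthetic claims generator
#'
#' Defines the full data-generating process for a claims database with known
#' causal structure: baseline covariates drawn to match the published cohort's
#' prevalences, a confounded logistic treatment-assignment model (colchicine
#' vs. NSAID prophylaxis at urate-lowering-therapy initiation), a per-interval
#' discontinuation (duration) model, a gout-flare model realized as steroid
#' dispensings, discrete 30-day-interval hazards for MACE, MALE and death, and
#' a disenrollment (censoring) process. Time is measured in integer days;
#' intervals are half-open 30-day blocks `[30k, 30(k+1))` from the index date.
#'
#' Defaults emulate the published study population: roughly 56% colchicine
#' share, mean prophylaxis duration of about 8 months (colchicine) and
#' 4.5 months (NSAID), and a 2-year composite risk of about 30%. The
#' `strategy_effect` entries multiply the per-interval hazards while on
#' colchicine (values below 1 are protective).
#'
#' @param n_patients number of patients to generate (>= 1).
#' @param seed integer root seed; child streams are derived per table.
#' @param study_start day index of study open (calendar origin of the window).
#' @param admin_end day index of administrative study close.
#' @param covariates named list of prevalences/means for baseline covariates
#'   (see defaults for required entries).
#' @param treatment list with `intercept` and named `coefs` (log-odds of
#'   colchicine vs NSAID on the raw covariate scale).
#' @param duration list with `stop_prob` (named per-arm per-interval
#'   discontinuation probability), `restart_prob` (per-interval probability
#'   of resuming prophylaxis after a stop; makes use intermittent, as
#'   dispensing histories in claims are) and `steroid_coef` (log-odds shift
#'   of both transitions for current-interval steroid use).
#' @param flare list with `base_prob` (per-interval steroid probability while
#'   on prophylaxis), `post_stop_logit` (log-odds shift after discontinuation)
#'   and `prior_steroid_logit` (shift for baseline steroid users).
#' @param hazards list with one entry per outcome (`mace`, `male`, `death`),
#'   each a list of `intercept`, named `coefs`, `steroid_logit` and
#'   `time_logit` (per-interval linear trend on the logit scale).
#' @param strategy_effect named multiplicative hazard modifiers for colchicine
#'   exposure, entries `mace`, `male`, `death`.
#' @param censoring list with `prob`, the per-interval disenrollment
#'   probability.
#'
#' @return An object of class `dgp_config`.
#' @seealso [simulate_cohort()], [simulate_counterfactual_risks()]
#' @export
dgp_config <- function(n_patients = 1820L,
                       seed = 1L,
                       study_start = 40000L,
                       admin_end = study_start + 4560L,
                       covariates = list(),
                       treatment = list(),
                       duration = list(),
                       flare = list(),
                       hazards = list(),
                       strategy_effect = c(mace = 0.9, male = 0.9, death = 1.0),
                       censoring = list()) {
  cov_def <- list(
    age_mean = 77, age_sd = 6.8, age_min = 67, age_max = 95,
    sex_male = 0.683, race_nonwhite = 0.092, obesity = 0.181,
    cad = 0.543, cerebrovascular = 0.118, heart_failure = 0.325,
    afib = 0.443, ckd13 = 0.164, copd = 0.224, diabetes = 0.521,
    insulin = 0.144,
    antihtn_probs = c(0.188, 0.406, 0.291, 0.115),
    beta_blocker = 0.718, statin = 0.761, antiplatelet = 0.144,
    cilostazol = 0.024, anticoagulation = 0.276,
    prior_male = 0.016, prior_mace = 0.056,
    rest_pain = 0.011, tissue_loss = 0.119,
    elixhauser_mean = 4.9, elixhauser_sd = 2.9,
    enrol_lead_blocks = c(7L, 120L),
    gout_encounter_prob = 0.09,
    febuxostat = 0.03, prior_steroid = 0.392
  )
  cov_def[names(covariates)] <- covariates

  # coefficients calibrated so the unweighted arm imbalances match the
  # published cohort's pattern (atrial fibrillation ~0.15, anticoagulation
  # ~0.13, heart failure ~0.10, Elixhauser ~0.22, enrolment time ~0.11)
  trt_def <- list(
    intercept = -1.69,
    coefs = c(afib = 0.80, anticoagulation = 0.65, heart_failure = 0.60,
              elixhauser = 0.08, age = 0.012, prior_steroid = 0.20,
              enrolment_time = -0.0035)
  )
  trt_def[names(treatment)] <- treatment

  # stop_prob gives a mean first-course duration of ~250 days (colchicine)
  # and ~135 days (NSAID); restart_prob makes use intermittent, as dispensing
  # histories in claims are
  dur_def <- list(stop_prob = c(colchicine = 0.12, NSAID = 0.22),
                  restart_prob = 0.05, steroid_coef = 0.5)
  dur_def[names(duration)] <- duration

  flare_def <- list(base_prob = 0.05, post_stop_logit = 0.8,
                    prior_steroid_logit = 0.5)
  flare_def[names(flare)] <- flare

  haz_def <- list(
    mace = list(
      intercept = -8.93,
      coefs = c(age = 0.04, cad = 0.5, afib = 0.3, elixhauser = 0.08,
                prior_mace = 0.6, diabetes = 0.2),
      steroid_logit = 0.35, time_logit = 0
    ),
    male = list(
      intercept = -8.23,
      coefs = c(age = 0.02, tissue_loss = 0.9, rest_pain = 0.7,
                prior_male = 0.8, diabetes = 0.3, elixhauser = 0.05),
      steroid_logit = 0.35, time_logit = 0
    ),
    death = list(
      intercept = -11.37,
      coefs = c(age = 0.07, heart_failure = 0.5, elixhauser = 0.12,
                ckd13 = 0.3, copd = 0.3),
      steroid_logit = 0.35, time_logit = 0
    )
  )
  for (nm in names(hazards)) {
    haz_def[[nm]][names(hazards[[nm]])] <- hazards[[nm]]
  }

  cens_def <- list(prob = 0.005)
  cens_def[names(censoring)] <- censoring

  cfg <- structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      study_start = as.integer(study_start), admin_end = as.integer(admin_end),
      covariates = cov_def, treatment = trt_def, duration = dur_def,
      flare = flare_def, hazards = haz_def,
      strategy_effect = strategy_effect, censoring = cens_def
    ),
    class = "dgp_config"
  )
  validate_dgp_config(cfg)
  cfg
}

validate_dgp_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 1) {
    stop_config("n_patients", "must be a positive integer")
  }
  if (cfg$admin_end <= cfg$study_start) {
    stop_config("admin_end", "must be after study_start")
  }
  cv <- cfg$covariates
  prob_fields <- c("sex_male", "race_nonwhite", "obesity", "cad",
                   "cerebrovascular", "heart_failure", "afib", "ckd13", "copd",
                   "diabetes", "insulin", "beta_blocker", "statin",
                   "antiplatelet", "cilostazol", "anticoagulation",
                   "prior_male", "prior_mace", "rest_pain", "tissue_loss",
                   "gout_encounter_prob", "febuxostat", "prior_steroid")
  for (f in prob_fields) check_prob(cv[[f]], paste0("covariates$", f))
  check_prob(cv$antihtn_probs, "covariates$antihtn_probs")
  if (abs(sum(cv$antihtn_probs) - 1) > 1e-6) {
    stop_config("covariates$antihtn_probs", "must sum to 1")
  }
  check_prob(cfg$duration$stop_prob, "duration$stop_prob")
  if (!all(c("colchicine", "NSAID") %in% names(cfg$duration$stop_prob))) {
    stop_config("duration$stop_prob", "needs entries colchicine and NSAID")
  }
  check_prob(cfg$duration$restart_prob, "duration$restart_prob")
  check_prob(cfg$flare$base_prob, "flare$base_prob")
  check_prob(cfg$censoring$prob, "censoring$prob")
  for (nm in c("mace", "male", "death")) {
    h <- cfg$hazards[[nm]]
    if (!is.numeric(h$intercept) || length(h$intercept) != 1) {
      stop_config(paste0("hazards$", nm, "$intercept"), "must be numeric")
    }
  }
  se <- cfg$strategy_effect
  if (!all(c("mace", "male", "death") %in% names(se)) ||
      any(!is.finite(se)) || any(se < 0)) {
    stop_config("strategy_effect",
                "needs non-negative entries mace, male and death")
  }
  invisible(cfg)
}

#' @export
print.dgp_config <- function(x, ...) {
  cat("<dgp_config>\n")
  cat(sprintf("  patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  study window: days [%d, %d] (%d 30-day blocks)\n",
              x$study_start, x$admin_end,
              (x$admin_end - x$study_start) %/% 30L))
  cat(sprintf("  strategy effect (hazard multipliers): mace %.2f, male %.2f, death %.2f\n",
              x$strategy_effect[["mace"]], x$strategy_effect[["male"]],
              x$strategy_effect[["death"]]))
  cat(sprintf("  discontinuation / interval: colchicine %.2f, NSAID %.2f\n",
              x$duration$stop_prob[["colchicine"]],
              x$duration$stop_prob[["NSAID"]]))
  invisible(x)
}
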