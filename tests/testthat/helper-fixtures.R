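# Fixtures built in code: a hand-traceable claims database and minimal
# cohort tables for the estimator modules.

# One-patient table builders --------------------------------------------------

empty_db <- function() {
  list(
    patients = data.frame(id = integer(), birth_date = numeric(),
                          sex = character(), race = character(),
                          elixhauser = numeric()),
    enrollment = data.frame(id = integer(), start_day = numeric(),
                            end_day = numeric()),
    diagnoses = data.frame(id = integer(), day = numeric(),
                           category = character()),
    dispensings = data.frame(id = integer(), day = numeric(),
                             drug_class = character(),
                             days_supplied = integer()),
    outcomes = data.frame(id = integer(), day = numeric(),
                          type = character()),
    deaths = data.frame(id = integer(), day = numeric())
  )
}

# A patient fully eligible at `index`: enrolled from index-600, gout and PAD
# on record, an encounter in the lookback, ULT at index and the prophylaxis
# drug at index.
add_patient <- function(db, id, index = 1000, age = 75, arm = "colchicine",
                        enroll_start = NULL, enroll_end = 5000,
                        with_dx = TRUE, with_prophylaxis = TRUE,
                        ult_day = index) {
  if (is.null(enroll_start)) enroll_start <- index - 600
  db$patients <- rbind(db$patients, data.frame(
    id = id, birth_date = index - round(age * 365.25), sex = "M",
    race = "white", elixhauser = 4))
  db$enrollment <- rbind(db$enrollment, data.frame(
    id = id, start_day = enroll_start, end_day = enroll_end))
  if (with_dx) {
    db$diagnoses <- rbind(db$diagnoses, data.frame(
      id = id, day = c(index - 300, index - 300, index - 50),
      category = c("gout", "PAD", "encounter")))
  }
  db$dispensings <- rbind(db$dispensings, data.frame(
    id = id, day = ult_day, drug_class = "ULT_allopurinol",
    days_supplied = 30L))
  if (with_prophylaxis) {
    db$dispensings <- rbind(db$dispensings, data.frame(
      id = id, day = ult_day, drug_class = arm, days_supplied = 30L))
  }
  db
}

add_dispensing <- function(db, id, day, drug_class, days_supplied = 30L) {
  db$dispensings <- rbind(db$dispensings, data.frame(
    id = id, day = day, drug_class = drug_class,
    days_supplied = days_supplied))
  db
}

as_claims_db <- function(db) structure(db, class = "claims_db")

# Minimal trial_cohort for estimator tests, bypassing the claims database.
# Times are absolute days with index_day = 0.
make_cohort <- function(arm, time = NULL, status = NULL,
                        mace_day = NA, male_day = NA, death_day = NA,
                        disenroll_day = NA, admin_end = 1e6) {
  n <- length(arm)
  if (!is.null(time)) {
    # encode (time, status) as death events vs disenrollment
    death_day <- ifelse(status == 1, time, NA_real_)
    disenroll_day <- ifelse(status == 0, time, NA_real_)
    mace_day <- male_day <- rep(NA_real_, n)
  }
  out <- data.frame(
    id = seq_len(n), index_day = 0, arm = arm,
    mace_day = rep_len(mace_day, n), male_day = rep_len(male_day, n),
    death_day = rep_len(death_day, n),
    disenroll_day = rep_len(disenroll_day, n),
    admin_end_day = rep_len(admin_end, n)
  )
  class(out) <- c("trial_cohort", "data.frame")
  out
}

# Small configs used across tests ---------------------------------------------

small_config <- function(n = 300, seed = 1, ...) {
  dgp_config(n_patients = n, seed = seed, ...)
}

# Null data-generating process: no colchicine effect and no steroid pathway
# into the hazards, so every treatment strategy has identical true risk.
fully_null_config <- function(n, seed) {
  dgp_config(
    n_patients = n, seed = seed,
    strategy_effect = c(mace = 1, male = 1, death = 1),
    hazards = list(mace = list(steroid_logit = 0),
                   male = list(steroid_logit = 0),
                   death = list(steroid_logit = 0))
  )
}

build_sim_cohort <- function(cfg, horizon = 730) {
  db <- simulate_cohort(cfg)
  spec <- eligibility_spec(cfg$study_start, cfg$admin_end)
  list(db = db, spec = spec, cohort = build_cohort(db, spec, horizon))
}
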