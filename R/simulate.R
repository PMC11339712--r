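# Synthetic claims generator: baseline covariates, confounded treatment
# assignment, and a discrete-time follow-up engine shared by the
# observational simulator and the counterfactual oracle.

lin_pred <- function(cov, coefs) {
  out <- numeric(nrow(cov))
  for (nm in names(coefs)) {
    if (is.null(cov[[nm]])) {
      stop_config(nm, "coefficient refers to an unknown covariate")
    }
    out <- out + coefs[[nm]] * cov[[nm]]
  }
  out
}

# Draw one baseline covariate table (one row per patient), including the
# index day (urate-lowering-therapy initiation) and derived time covariates.
draw_baseline <- function(cfg, n = cfg$n_patients) {
  cv <- cfg$covariates
  rbin <- function(p) stats::rbinom(n, 1L, p)
  age <- pmin(pmax(stats::rnorm(n, cv$age_mean, cv$age_sd), cv$age_min),
              cv$age_max)
  index_day <- cfg$study_start +
    floor(stats::runif(n) * (cfg$admin_end - cfg$study_start + 1))
  lead_blocks <- cv$enrol_lead_blocks[1] +
    floor(stats::runif(n) * (cv$enrol_lead_blocks[2] - cv$enrol_lead_blocks[1] + 1))
  elix <- pmin(pmax(round(stats::rnorm(n, cv$elixhauser_mean, cv$elixhauser_sd)), 0), 15)
  data.frame(
    id = seq_len(n),
    index_day = index_day,
    age = age,
    sex_male = rbin(cv$sex_male),
    race_nonwhite = rbin(cv$race_nonwhite),
    obesity = rbin(cv$obesity),
    cad = rbin(cv$cad),
    cerebrovascular = rbin(cv$cerebrovascular),
    heart_failure = rbin(cv$heart_failure),
    afib = rbin(cv$afib),
    ckd13 = rbin(cv$ckd13),
    copd = rbin(cv$copd),
    diabetes = rbin(cv$diabetes),
    insulin = rbin(cv$insulin),
    antihtn_count = sample.int(4L, n, replace = TRUE,
                               prob = cv$antihtn_probs) - 1L,
    beta_blocker = rbin(cv$beta_blocker),
    statin = rbin(cv$statin),
    antiplatelet = rbin(cv$antiplatelet),
    cilostazol = rbin(cv$cilostazol),
    anticoagulation = rbin(cv$anticoagulation),
    prior_male = rbin(cv$prior_male),
    prior_mace = rbin(cv$prior_mace),
    rest_pain = rbin(cv$rest_pain),
    tissue_loss = rbin(cv$tissue_loss),
    elixhauser = elix,
    calendar_time = (index_day - cfg$study_start) %/% 30L,
    enrolment_time = lead_blocks,
    gout_encounters = rbin(cv$gout_encounter_prob),
    febuxostat = rbin(cv$febuxostat),
    prior_steroid = rbin(cv$prior_steroid)
  )
}

assign_treatment <- function(cov, cfg) {
  p <- expit(cfg$treatment$intercept + lin_pred(cov, cfg$treatment$coefs))
  ifelse(stats::runif(nrow(cov)) < p, "colchicine", "NSAID")
}

# Discrete-time follow-up engine. All days are relative to the index date;
# interval k covers days [30k, 30(k+1)).
#
# strategy:
#   "observational"              arm as assigned, natural discontinuation,
#                                disenrollment active
#   "always-colchicine",
#   "colchicine-indefinite"      colchicine exposure forced in every interval
#   "always-NSAID"               never exposed to colchicine
#   "colchicine-90-days-then-stop" exposed in intervals 0-2 only
#   "initiate-colchicine",
#   "initiate-NSAID"             natural discontinuation after initiating the
#                                named drug (the initiation counterfactual)
#
# K_i gives, per patient, the number of intervals before administrative end;
# max_k the number of intervals to simulate.
sim_followup <- function(cov, arm, cfg, strategy, K_i, max_k) {
  n <- nrow(cov)
  observational <- strategy == "observational"
  natural_stop <- observational ||
    strategy %in% c("initiate-colchicine", "initiate-NSAID")
  if (strategy == "initiate-colchicine") arm <- rep("colchicine", n)
  if (strategy == "initiate-NSAID") arm <- rep("NSAID", n)

  # prophylaxis on/off state machine: everyone starts on; stop and restart
  # transitions are evaluated at each interval start (natural modes only)
  on_state <- rep(TRUE, n)
  stop_int <- rep(Inf, n)  # first off-interval (reported as truth)
  if (strategy == "colchicine-90-days-then-stop") stop_int <- rep(3, n)

  haz <- cfg$hazards
  lp <- list(mace = haz$mace$intercept + lin_pred(cov, haz$mace$coefs),
             male = haz$male$intercept + lin_pred(cov, haz$male$coefs),
             death = haz$death$intercept + lin_pred(cov, haz$death$coefs))
  eff <- cfg$strategy_effect

  flare <- cfg$flare
  flare_base <- stats::qlogis(flare$base_prob) +
    flare$prior_steroid_logit * cov$prior_steroid
  clamp_q <- function(p) stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  stopq <- clamp_q(cfg$duration$stop_prob[arm])
  restartq <- clamp_q(cfg$duration$restart_prob)
  cens_p <- cfg$censoring$prob

  alive <- rep(TRUE, n)
  enrolled <- rep(TRUE, n)
  mace_day <- male_day <- death_day <- disenroll_day <- rep(NA_real_, n)
  on_treat <- matrix(FALSE, n, max_k)
  steroid <- matrix(FALSE, n, max_k)

  for (k in seq_len(max_k) - 1L) {
    active <- alive & enrolled & (k < K_i)
    if (!any(active)) break

    if (observational && cens_p > 0) {
      dis <- active & (stats::runif(n) < cens_p)
      disenroll_day[dis] <- 30 * k
      enrolled[dis] <- FALSE
      active <- active & !dis
    }

    # flares depend on being off prophylaxis in the previous interval
    stopped_prev <- if (natural_stop) !on_state else stop_int <= k - 1
    p_st <- expit(flare_base + flare$post_stop_logit * stopped_prev)
    st <- active & (stats::runif(n) < p_st)
    steroid[, k + 1L] <- st

    if (natural_stop && k >= 1) {
      shift <- cfg$duration$steroid_coef * st
      p_stop <- expit(stopq + shift)
      p_restart <- expit(restartq + shift)
      u <- stats::runif(n)
      newstop <- active & on_state & (u < p_stop)
      restart <- active & !on_state & (u < p_restart)
      on_state[newstop] <- FALSE
      on_state[restart] <- TRUE
      stop_int[newstop] <- pmin(stop_int[newstop], k)
    }
    on_now <- if (natural_stop) {
      active & on_state
    } else {
      switch(strategy,
             "always-colchicine" = ,
             "colchicine-indefinite" = ,
             "always-NSAID" = active,
             "colchicine-90-days-then-stop" = active & (k < 3))
    }
    on_treat[, k + 1L] <- on_now

    on_colch <- switch(
      strategy,
      "observational" = on_now & (arm == "colchicine"),
      "always-colchicine" = ,
      "colchicine-indefinite" = active,
      "always-NSAID" = ,
      "initiate-NSAID" = rep(FALSE, n),
      "colchicine-90-days-then-stop" = active & (k < 3),
      "initiate-colchicine" = on_now
    )

    dth_new <- rep(FALSE, n)
    for (type in c("death", "mace", "male")) {
      done <- switch(type, death = !is.na(death_day),
                     mace = !is.na(mace_day), male = !is.na(male_day))
      elig <- active & !done
      h <- expit(lp[[type]] + haz[[type]]$steroid_logit * st +
                   haz[[type]]$time_logit * k)
      h <- pmin(0.99, h * ifelse(on_colch, eff[[type]], 1))
      hit <- elig & (stats::runif(n) < h)
      if (any(hit)) {
        day <- 30 * k + floor(stats::runif(sum(hit)) * 30)
        day[day == 0] <- 1  # keep post-index events strictly after the index
        if (type == "death") {
          death_day[hit] <- day
          dth_new <- hit
        } else if (type == "mace") {
          mace_day[hit] <- day
        } else {
          male_day[hit] <- day
        }
      }
    }
    # a death in this interval invalidates same-interval events after it
    if (any(dth_new)) {
      bad_m <- dth_new & !is.na(mace_day) & mace_day > death_day &
        mace_day >= 30 * k
      mace_day[bad_m] <- NA_real_
      bad_l <- dth_new & !is.na(male_day) & male_day > death_day &
        male_day >= 30 * k
      male_day[bad_l] <- NA_real_
      alive <- alive & is.na(death_day)
    }
  }
  list(mace_day = mace_day, male_day = male_day, death_day = death_day,
       disenroll_day = disenroll_day, stop_int = stop_int,
       on_treat = on_treat, steroid = steroid)
}

#' Simulate a synthetic claims database
#'
#' Generates a multi-table claims database (patients, enrollment, diagnoses,
#' dispensings, outcomes, deaths) from a [dgp_config()]. Every patient is a
#' new user of urate-lowering therapy with gout and PAD diagnoses on record
#' before the index dispensing, a clean 6-month washout, a prophylaxis course
#' (colchicine or NSAID) realized as abutting 30-day dispensings until the
#' sampled discontinuation interval, steroid dispensings marking gout flares,
#' and discrete-hazard outcome events. Identical `(config, seed)` pairs give
#' identical databases.
#'
#' @param config a [dgp_config()].
#' @return A `claims_db` object: a named list of data.frames
#'   (`patients`, `enrollment`, `diagnoses`, `dispensings`, `outcomes`,
#'   `deaths`). The generator-side truth (assigned arm, index day,
#'   discontinuation interval) is attached as `attr(db, "truth")` for
#'   verification harnesses.
#' @export
#' @examples
#' db <- simulate_cohort(dgp_config(n_patients = 50, seed = 7))
#' sapply(db, nrow)
simulate_cohort <- function(config) {
  validate_dgp_config(config)
  cfg <- config
  n <- cfg$n_patients

  cov <- with_seed(derive_seed(cfg$seed, 1L), draw_baseline(cfg))
  arm <- with_seed(derive_seed(cfg$seed, 2L), assign_treatment(cov, cfg))

  K_i <- pmax(ceiling((cfg$admin_end - cov$index_day) / 30), 0L)
  max_k <- max(K_i, 1L)
  fu <- with_seed(derive_seed(cfg$seed, 3L),
                  sim_followup(cov, arm, cfg, "observational", K_i, max_k))

  with_seed(derive_seed(cfg$seed, 4L), {
    idx <- cov$index_day
    lb <- function(m) idx[m] - (floor(stats::runif(sum(m)) * 183) + 1)

    patients <- data.frame(
      id = cov$id,
      birth_date = idx - round(cov$age * 365.25),
      sex = ifelse(cov$sex_male == 1, "M", "F"),
      race = ifelse(cov$race_nonwhite == 1, "non-white", "white"),
      elixhauser = cov$elixhauser
    )

    end_day <- ifelse(!is.na(fu$death_day), idx + fu$death_day,
                      ifelse(!is.na(fu$disenroll_day),
                             idx + fu$disenroll_day, cfg$admin_end))
    enrollment <- data.frame(
      id = cov$id,
      start_day = idx - cov$enrolment_time * 30L,
      end_day = as.integer(end_day)
    )

    # diagnoses: qualifying gout/PAD before the lookback window, an encounter
    # inside it, comorbidity codes inside it, extra gout encounters per the
    # gout-severity covariate
    all_true <- rep(TRUE, n)
    dx_list <- list(
      data.frame(id = cov$id, day = idx - (184 + floor(stats::runif(n) * 400)),
                 category = "gout"),
      data.frame(id = cov$id, day = idx - (184 + floor(stats::runif(n) * 400)),
                 category = "PAD"),
      data.frame(id = cov$id, day = lb(all_true), category = "encounter")
    )
    dx_map <- c(cad = "CAD", heart_failure = "HF", afib = "AF",
                ckd13 = "CKD1-3", copd = "COPD", diabetes = "diabetes",
                obesity = "obesity", cerebrovascular = "cerebrovascular",
                rest_pain = "rest_pain", tissue_loss = "tissue_loss")
    for (nm in names(dx_map)) {
      m <- cov[[nm]] == 1
      if (any(m)) {
        dx_list[[length(dx_list) + 1L]] <-
          data.frame(id = cov$id[m], day = lb(m), category = dx_map[[nm]])
      }
    }
    m <- cov$gout_encounters >= 1
    if (any(m)) {
      dx_list[[length(dx_list) + 1L]] <-
        data.frame(id = cov$id[m], day = lb(m), category = "gout")
    }
    diagnoses <- do.call(rbind, dx_list)

    # dispensings: index ULT, prophylaxis course, flare steroids, baseline meds
    disp_list <- list(
      data.frame(id = cov$id, day = idx,
                 drug_class = ifelse(cov$febuxostat == 1, "ULT_febuxostat",
                                     "ULT_allopurinol"),
                 days_supplied = 30L)
    )
    course <- which(fu$on_treat, arr.ind = TRUE)
    if (nrow(course)) {
      disp_list[[2L]] <- data.frame(
        id = cov$id[course[, 1]],
        day = idx[course[, 1]] + 30L * (course[, 2] - 1L),
        drug_class = ifelse(arm[course[, 1]] == "colchicine",
                            "colchicine", "NSAID"),
        days_supplied = 30L
      )
    }
    ster <- which(fu$steroid, arr.ind = TRUE)
    if (nrow(ster)) {
      disp_list[[length(disp_list) + 1L]] <- data.frame(
        id = cov$id[ster[, 1]],
        # +1 keeps interval-0 flare steroids out of the baseline lookback
        day = idx[ster[, 1]] + 30L * (ster[, 2] - 1L) + 1L,
        drug_class = "steroid", days_supplied = 10L
      )
    }
    med_map <- c(statin = "statin", beta_blocker = "beta_blocker",
                 antiplatelet = "antiplatelet", anticoagulation = "anticoagulant",
                 cilostazol = "cilostazol", insulin = "insulin",
                 prior_steroid = "steroid")
    for (nm in names(med_map)) {
      m <- cov[[nm]] == 1
      if (any(m)) {
        disp_list[[length(disp_list) + 1L]] <- data.frame(
          id = cov$id[m], day = lb(m), drug_class = med_map[[nm]],
          days_supplied = 30L
        )
      }
    }
    for (j in 1:3) {
      m <- cov$antihtn_count >= j
      if (any(m)) {
        disp_list[[length(disp_list) + 1L]] <- data.frame(
          id = cov$id[m], day = lb(m),
          drug_class = paste0("antihypertensive_", j), days_supplied = 30L
        )
      }
    }
    dispensings <- do.call(rbind, disp_list)

    out_list <- list()
    m <- !is.na(fu$mace_day)
    if (any(m)) {
      out_list[[length(out_list) + 1L]] <-
        data.frame(id = cov$id[m], day = idx[m] + fu$mace_day[m], type = "MACE")
    }
    m <- !is.na(fu$male_day)
    if (any(m)) {
      out_list[[length(out_list) + 1L]] <-
        data.frame(id = cov$id[m], day = idx[m] + fu$male_day[m], type = "MALE")
    }
    m <- cov$prior_mace == 1
    if (any(m)) {
      out_list[[length(out_list) + 1L]] <-
        data.frame(id = cov$id[m], day = lb(m), type = "MACE")
    }
    m <- cov$prior_male == 1
    if (any(m)) {
      out_list[[length(out_list) + 1L]] <-
        data.frame(id = cov$id[m], day = lb(m), type = "MALE")
    }
    outcomes <- if (length(out_list)) {
      do.call(rbind, out_list)
    } else {
      data.frame(id = integer(), day = numeric(), type = character())
    }

    m <- !is.na(fu$death_day)
    deaths <- data.frame(id = cov$id[m], day = idx[m] + fu$death_day[m])

    db <- structure(
      list(patients = patients, enrollment = enrollment,
           diagnoses = diagnoses, dispensings = dispensings,
           outcomes = outcomes, deaths = deaths),
      class = "claims_db"
    )
    for (nm in names(db)) rownames(db[[nm]]) <- NULL
    attr(db, "truth") <- data.frame(
      id = cov$id, index_day = idx, arm = arm,
      stop_interval = fu$stop_int
    )
    validate_claims_db(db)
    db
  })
}

#' Validate a claims database
#'
#' Checks the structural invariants of a `claims_db`: required tables and
#' columns, foreign keys into the patients table, non-overlapping enrollment
#' spans, positive days supplied, at most one death per patient, and
#' non-negative day indices.
#'
#' @param db a `claims_db` (list of the six claims tables).
#' @return `db`, invisibly; errors describe the violated invariant.
#' @export
validate_claims_db <- function(db) {
  needed <- c("patients", "enrollment", "diagnoses", "dispensings",
              "outcomes", "deaths")
  if (!all(needed %in% names(db))) {
    stop("claims_db must contain tables: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  ids <- db$patients$id
  if (anyDuplicated(ids)) stop("duplicate patient ids", call. = FALSE)
  for (tb in c("enrollment", "diagnoses", "dispensings", "outcomes", "deaths")) {
    if (nrow(db[[tb]]) && !all(db[[tb]]$id %in% ids)) {
      stop(sprintf("table %s references unknown patient ids", tb),
           call. = FALSE)
    }
  }
  for (tb in needed) {
    day_cols <- intersect(names(db[[tb]]),
                          c("day", "start_day", "end_day", "birth_date"))
    for (cl in day_cols) {
      if (nrow(db[[tb]]) && any(db[[tb]][[cl]] < 0, na.rm = TRUE)) {
        stop(sprintf("negative day index in %s$%s", tb, cl), call. = FALSE)
      }
    }
  }
  if (nrow(db$dispensings) && any(db$dispensings$days_supplied < 1)) {
    stop("days_supplied must be >= 1", call. = FALSE)
  }
  if (anyDuplicated(db$deaths$id)) {
    stop("at most one death per patient", call. = FALSE)
  }
  en <- db$enrollment
  if (nrow(en) > 1) {
    en <- en[order(en$id, en$start_day), ]
    same <- en$id[-1] == en$id[-nrow(en)]
    if (any(same & en$start_day[-1] <= en$end_day[-nrow(en)])) {
      stop("overlapping enrollment spans", call. = FALSE)
    }
  }
  invisible(db)
}

#' @export
print.claims_db <- function(x, ...) {
  cat("<claims_db>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %7d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Write / read a claims database as CSV files
#'
#' The six tables are written as headered comma-delimited files
#' (`patients.csv`, `enrollment.csv`, `diagnoses.csv`, `dispensings.csv`,
#' `outcomes.csv`, `deaths.csv`) into `dir`.
#'
#' @param db a `claims_db`.
#' @param dir directory (created if missing).
#' @return `write_claims_db` returns `dir` invisibly; `read_claims_db`
#'   returns a validated `claims_db`.
#' @export
write_claims_db <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(db)) {
    utils::write.csv(db[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_claims_db
#' @export
read_claims_db <- function(dir) {
  tbs <- c("patients", "enrollment", "diagnoses", "dispensings",
           "outcomes", "deaths")
  db <- lapply(tbs, function(nm) {
    utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                    stringsAsFactors = FALSE)
  })
  names(db) <- tbs
  db <- structure(db, class = "claims_db")
  validate_claims_db(db)
  db
}
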