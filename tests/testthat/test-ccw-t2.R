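# Clone-censor-weight machinery: discretization, protocol adjudication,
# censoring weights, pooled logistic outcome model.

# db with one colchicine initiator whose course covers [0, cov_end) days
course_db <- function(cov_end, index = 1000, enroll_end = 5000,
                      extra_colch_days = NULL) {
  db <- add_patient(empty_db(), 1, index = index, enroll_end = enroll_end)
  d <- index + 30
  while (d < index + cov_end) {
    db <- add_dispensing(db, 1, day = d, drug_class = "colchicine")
    d <- d + 30
  }
  for (d in extra_colch_days) {
    db <- add_dispensing(db, 1, day = index + d, drug_class = "colchicine")
  }
  as_claims_db(db)
}

cohort_from <- function(db, spec = eligibility_spec(0, 5000), horizon = 730) {
  build_cohort(db, spec, horizon)
}

test_that("cloning yields two clones per patient and day-interval arithmetic", {
  sim <- build_sim_cohort(small_config(n = 60, seed = 61))
  pi <- clone_and_discretize(sim$cohort, sim$db, horizon = 720)
  expect_equal(sum(pi$k == 0), 2 * nrow(sim$cohort))
  expect_setequal(unique(pi$clone), c("long_term", "short_term"))
  expect_error(clone_and_discretize(sim$cohort, sim$db, horizon = 730),
               "multiple")
})

test_that("100 days of follow-up discretize to four intervals", {
  db <- course_db(1000, enroll_end = 1100)  # disenrolls 100 days post-index
  cohort <- cohort_from(db, eligibility_spec(0, 5000))
  pi <- clone_and_discretize(cohort, db, horizon = 720, grace_days = 0)
  long <- pi[pi$clone == "long_term", ]
  expect_equal(long$k, 0:3)
  expect_true(long$censor[long$k == 3])
})

test_that("events land in the interval containing their day", {
  db <- course_db(1000)
  db$outcomes <- rbind(db$outcomes,
                       data.frame(id = 1, day = 1045, type = "MACE"))
  cohort <- cohort_from(db)
  pi <- clone_and_discretize(cohort, db, horizon = 720, grace_days = 0)
  long <- pi[pi$clone == "long_term", ]
  expect_equal(long$k[long$mace_k], 1)
})

test_that("protocol adjudication matches the hand traces (grace 0)", {
  # coverage days 0-59: both clones censored in interval 2
  pi <- adjudicate_protocol(clone_and_discretize(
    cohort_from(course_db(60)), course_db(60), horizon = 720,
    grace_days = 0))
  for (cl in c("long_term", "short_term")) {
    rows <- pi[pi$clone == cl, ]
    expect_equal(max(rows$k), 2)
    expect_true(rows$deviation[rows$k == 2])
  }

  # coverage days 0-89: long censored at interval 3, short never deviates
  pi <- adjudicate_protocol(clone_and_discretize(
    cohort_from(course_db(90)), course_db(90), horizon = 720,
    grace_days = 0))
  long <- pi[pi$clone == "long_term", ]
  expect_equal(max(long$k), 3)
  expect_true(long$deviation[long$k == 3])
  short <- pi[pi$clone == "short_term", ]
  expect_false(any(short$deviation))

  # coverage days 0-300 with follow-up ending at day 300: long never
  # deviates; short censored in the first interval at/after day 90
  db <- course_db(300, enroll_end = 1300)
  pi <- adjudicate_protocol(clone_and_discretize(
    cohort_from(db), db, horizon = 720, grace_days = 0))
  long <- pi[pi$clone == "long_term", ]
  expect_false(any(long$deviation))
  short <- pi[pi$clone == "short_term", ]
  expect_true(short$deviation[short$k == 3])
  expect_equal(max(short$k), 3)
})

test_that("the grace period defers deviation by bridging refill gaps", {
  # coverage 0-300, grace 30: short clone deviates at the interval of the
  # first dispensing at/after day 90 + 30 = interval 4
  db <- course_db(300, enroll_end = 2000)
  pi <- adjudicate_protocol(clone_and_discretize(
    cohort_from(db), db, horizon = 720, grace_days = 30))
  short <- pi[pi$clone == "short_term", ]
  expect_true(short$deviation[short$k == 4])
  # long arm: coverage ends day 300, grace extends compliance to day 330,
  # deviation in interval 11
  long <- pi[pi$clone == "long_term", ]
  expect_true(long$deviation[long$k == 11])
})

test_that("a patient who never initiates colchicine deviates at interval 0", {
  db <- add_patient(empty_db(), 1, index = 1000, arm = "NSAID")
  db <- as_claims_db(db)
  pi <- adjudicate_protocol(clone_and_discretize(
    cohort_from(db), db, horizon = 720, grace_days = 30))
  expect_equal(nrow(pi), 2)
  expect_true(all(pi$k == 0 & pi$deviation))
})

test_that("cumulative weights multiply the stabilized ratios", {
  sim <- build_sim_cohort(small_config(n = 40, seed = 63))
  pi <- adjudicate_protocol(clone_and_discretize(sim$cohort, sim$db,
                                                 horizon = 720))
  # all ratios 1 -> all weights 1
  w1 <- compute_tv_weights(pi, 99)
  expect_true(all(w1$weight == 1))
  # override one clone's probabilities: den 0.8, num 0.9 each interval
  one <- pi$id == pi$id[1] & pi$clone == "long_term"
  pi$p_den[one] <- 0.8
  pi$p_num[one] <- 0.9
  w2 <- compute_tv_weights(pi, NULL)
  got <- w2$weight[one][order(w2$k[one])]
  expect_equal(got[1:2], c(0.9 / 0.8, (0.9 / 0.8)^2), tolerance = 1e-12)
  pi$p_den[one][1] <- 0
  expect_error(compute_tv_weights(pi, 99), "positivity")
})

test_that("no deviations anywhere degenerate the censoring weights to 1", {
  # one long-term complier and one exact 90-day stopper, horizon inside
  # both compliance windows
  db <- course_db(720, enroll_end = 2000)
  db <- add_patient(db, 2, index = 1000, arm = "colchicine",
                    enroll_end = 2000)
  db <- add_dispensing(db, 2, day = 1030, drug_class = "colchicine")
  db <- add_dispensing(db, 2, day = 1060, drug_class = "colchicine")
  db <- as_claims_db(db)
  cohort <- cohort_from(db)
  pi <- adjudicate_protocol(clone_and_discretize(cohort, db, horizon = 720,
                                                 grace_days = 0))
  long1 <- pi$clone == "long_term" & pi$id == 1
  expect_false(any(pi$deviation[long1]))
  expect_message(out <- fit_censoring_models(pi[long1 | (pi$clone ==
    "short_term" & pi$id == 2), , drop = FALSE], cohort),
    "degenerate")
  expect_true(all(out$p_num == 1) && all(out$p_den == 1))
})

test_that("the censoring model recovers the steroid effect on discontinuation", {
  # grace 0 aligns the deviation interval with the steroid draw that drove
  # the stop decision; steroid_coef > 0 means steroid use predicts
  # deviation, i.e. a negative coefficient on remaining uncensored
  cfg <- dgp_config(n_patients = 5000, seed = 65,
                    duration = list(steroid_coef = 1.5))
  sim <- build_sim_cohort(cfg)
  pi <- adjudicate_protocol(clone_and_discretize(sim$cohort, sim$db,
                                                 horizon = 720,
                                                 grace_days = 0))
  dat <- cbind(pi, sim$cohort[match(pi$id, sim$cohort$id),
                              trial_covariates()$name])
  # k >= 1 rows are colchicine initiators still at risk of stopping
  m <- dat$clone == "long_term" & !dat$post_death & dat$k >= 1
  fit <- suppressWarnings(glm(I(1 - deviation) ~ steroid + k,
                              data = dat[m, ], family = binomial()))
  expect_lt(coef(fit)[["steroidTRUE"]], 0)
  expect_gt(abs(coef(fit)[["steroidTRUE"]]) /
              summary(fit)$coefficients["steroidTRUE", 2], 3)
})

test_that("pooled logistic model recovers a null constant hazard", {
  cfg <- fully_null_config(3000, seed = 67)
  sim <- build_sim_cohort(cfg)
  pi <- adjudicate_protocol(clone_and_discretize(sim$cohort, sim$db,
                                                 horizon = 720))
  pi <- suppressMessages(fit_censoring_models(pi, sim$cohort))
  pi <- compute_tv_weights(pi, 99)
  fit <- fit_outcome_model(pi, outcome_definition("composite"))
  sm <- summary(fit$fit)$coefficients
  for (nm in c("arm_long", "arm_long:k")) {
    expect_lt(abs(sm[nm, "Estimate"] / sm[nm, "Std. Error"]), 3.5)
  }
})

test_that("saturated-time fit reproduces empirical interval hazards", {
  sim <- build_sim_cohort(small_config(n = 500, seed = 69))
  pi <- adjudicate_protocol(clone_and_discretize(sim$cohort, sim$db,
                                                 horizon = 360))
  fit <- fit_outcome_model(pi, outcome_definition("composite"),
                           time_terms = "saturated")
  # empirical hazards from the retained long-arm rows
  dat <- fit$fit$data
  long <- dat[dat$arm_long == 1, ]
  emp <- tapply(long$event, long$k, mean)
  curves <- predict_risk_curves(fit, 360)
  risk_emp <- 1 - cumprod(1 - emp)
  expect_equal(curves$long_term$risk[-1], unname(risk_emp),
               tolerance = 1e-8)
})

test_that("predicted risk curves follow the closed form and are monotone", {
  # constant hazard 0.01 per interval: 100 unit-weight rows per interval,
  # exactly one with the event
  K <- 24
  rows <- expand.grid(i = 1:100, k = 0:(K - 1))
  one_arm <- function(arm_label, id_offset) data.frame(
    id = id_offset + seq_len(nrow(rows)), clone = arm_label, k = rows$k,
    steroid = FALSE, on_colch = TRUE,
    mace_k = rows$i == 1, male_k = FALSE, death_k = FALSE,
    post_death = FALSE, censor = FALSE, deviation = FALSE,
    disc_day = Inf, late_day = Inf, death_rel = Inf,
    mace_rel = ifelse(rows$i == 1, 30 * rows$k + 1, Inf), male_rel = Inf,
    t_end = 720, weight = 1, p_num = 1, p_den = 1
  )
  pi <- rbind(one_arm("long_term", 0), one_arm("short_term", 10000))
  attr(pi, "interval_days") <- 30L
  attr(pi, "horizon") <- 720L
  class(pi) <- c("person_intervals", "data.frame")
  fit <- fit_outcome_model(pi, outcome_definition("mace"),
                           time_terms = "saturated")
  curves <- predict_risk_curves(fit, 720)
  expect_equal(risk_at(curves$long_term, 720), 1 - 0.99^24,
               tolerance = 1e-8)
  expect_equal(risk_at(curves$short_term, 720), 1 - 0.99^24,
               tolerance = 1e-8)
  expect_true(all(diff(curves$long_term$risk) >= -1e-12))
})

test_that("run_trial2 produces estimates for all outcomes", {
  sim <- build_sim_cohort(small_config(n = 500, seed = 71))
  t2 <- suppressMessages(run_trial2(sim$cohort, sim$db))
  expect_equal(nrow(t2$estimates), 6)
  expect_true(all(t2$estimates$risk_treated >= 0 &
                    t2$estimates$risk_treated <= 1))
  t2b <- suppressMessages(run_trial2(sim$cohort, sim$db,
                                     clone_scope = "colchicine"))
  expect_equal(sum(t2b$intervals$k == 0),
               2 * sum(sim$cohort$arm == "colchicine"))
})
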