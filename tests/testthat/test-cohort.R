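# Cohort construction: new-user identification, eligibility attrition,
# covariate assembly, outcome ascertainment.

spec_default <- function(start = 0, end = 5000) eligibility_spec(start, end)

test_that("find_initiators pairs ULT initiation with the prophylaxis arm", {
  db <- as_claims_db(add_patient(empty_db(), 1, index = 1000))
  cand <- find_initiators(db, spec_default())
  expect_equal(cand$id, 1)
  expect_equal(cand$index_day, 1000)
  expect_equal(cand$arm, "colchicine")
})

test_that("recent prophylaxis use violates the washout", {
  db <- add_patient(empty_db(), 1, index = 1000)
  db <- add_dispensing(db, 1, day = 1000 - 60, drug_class = "colchicine")
  cand <- find_initiators(as_claims_db(db), spec_default())
  expect_equal(nrow(cand), 0)
  # the same dispensing outside the 183-day washout is fine
  db2 <- add_patient(empty_db(), 1, index = 1000)
  db2 <- add_dispensing(db2, 1, day = 1000 - 200, drug_class = "colchicine")
  expect_equal(nrow(find_initiators(as_claims_db(db2), spec_default())), 1)
})

test_that("same-window colchicine and NSAID dispensing excludes the patient", {
  db <- add_patient(empty_db(), 1, index = 1000)
  db <- add_dispensing(db, 1, day = 1000, drug_class = "NSAID")
  cand <- find_initiators(as_claims_db(db), spec_default())
  expect_equal(nrow(cand), 0)
})

test_that("eligibility drops are attributed to the first failing criterion", {
  spec <- eligibility_spec(500, 5000)
  db <- empty_db()
  # p1 fails the study window
  db <- add_patient(db, 1, index = 400)
  # p2 lacks enrollment covering the lookback
  db <- add_patient(db, 2, index = 1000, enroll_start = 1000 - 100)
  # p3 has qualifying diagnoses but no health-system use in the lookback
  db <- add_patient(db, 3, index = 1000, with_dx = FALSE)
  db$diagnoses <- rbind(db$diagnoses, data.frame(
    id = 3, day = c(700, 700), category = c("gout", "PAD")))
  # p4 is 65.9 years old at index
  db <- add_patient(db, 4, index = 1000, age = 65.9)
  # p5 lacks the gout diagnosis
  db <- add_patient(db, 5, index = 1000, with_dx = FALSE)
  db$diagnoses <- rbind(db$diagnoses, data.frame(
    id = 5, day = c(700, 950), category = c("PAD", "encounter")))
  # p6 has advanced CKD in the lookback
  db <- add_patient(db, 6, index = 1000)
  db$diagnoses <- rbind(db$diagnoses, data.frame(
    id = 6, day = 990, category = "CKD4-5/ESKD"))
  # p7, p8 pass
  db <- add_patient(db, 7, index = 1000)
  db <- add_patient(db, 8, index = 1200, arm = "NSAID")
  db <- as_claims_db(db)

  cand <- find_initiators(db, spec)
  expect_equal(nrow(cand), 8)
  elig <- apply_eligibility(db, cand, spec)
  at <- attr(elig, "attrition")
  expect_equal(sort(elig$id), c(7, 8))
  expect_equal(unname(at[c("study_window", "enrollment", "health_system_use",
                           "age", "required_dx", "exclusion_dx")]),
               rep(1L, 6))
  # attrition counts sum: candidates = eligible + per-criterion drops
  expect_equal(unname(at[["candidates"]]),
               unname(at[["eligible"]]) + sum(at[2:7]))
})

test_that("covariates are assembled from the lookback window", {
  db <- add_patient(empty_db(), 1, index = 1000)
  db <- add_dispensing(db, 1, day = 1000 - 30, drug_class = "steroid")
  db <- add_patient(db, 2, index = 1000, arm = "NSAID")
  db <- as_claims_db(db)
  spec <- spec_default()
  cohort <- assemble_covariates(db, find_initiators(db, spec), spec)
  expect_equal(cohort$prior_steroid, c(1L, 0L))
  expect_equal(cohort$enrolment_time, c(20L, 20L))  # 600 days = 20 blocks
  expect_equal(cohort$antihtn_count, c(0, 0))
  expect_equal(cohort$febuxostat, c(0L, 0L))
  expect_error(assemble_covariates(db, data.frame(id = 99, index_day = 1,
                                                  arm = "colchicine"), spec),
               "absent")
})

test_that("follow-up ascertainment applies the min rule with event ties", {
  spec <- spec_default(end = 2000)
  db <- add_patient(empty_db(), 1, index = 1000, enroll_end = 2000)
  # p2: MALE and death on the same day
  db <- add_patient(db, 2, index = 1000, arm = "NSAID", enroll_end = 1010)
  db$outcomes <- rbind(db$outcomes, data.frame(id = 2, day = 1010,
                                               type = "MALE"))
  db$deaths <- rbind(db$deaths, data.frame(id = 2, day = 1010))
  # p3: death at +50, MACE would have been at +100
  db <- add_patient(db, 3, index = 1000, enroll_end = 1050)
  db$outcomes <- rbind(db$outcomes, data.frame(id = 3, day = 1100,
                                               type = "MACE"))
  db$deaths <- rbind(db$deaths, data.frame(id = 3, day = 1050))
  db <- as_claims_db(db)
  cohort <- build_cohort(db, spec, horizon_days = 730)

  p1 <- cohort[cohort$id == 1, ]
  expect_true(is.na(p1$mace_day) && is.na(p1$death_day) &&
                is.na(p1$disenroll_day))
  expect_equal(p1$admin_end_day, 2000)

  p2 <- cohort[cohort$id == 2, ]
  expect_equal(p2$male_day, 1010)
  expect_equal(p2$death_day, 1010)
  comp2 <- min(p2$mace_day, p2$male_day, p2$death_day, na.rm = TRUE)
  expect_equal(comp2 - p2$index_day, 10)

  p3 <- cohort[cohort$id == 3, ]
  comp3 <- min(p3$mace_day, p3$male_day, p3$death_day, na.rm = TRUE)
  expect_equal(comp3 - p3$index_day, 50)  # death precedes the later MACE
})

test_that("no covariate uses post-index information", {
  sim <- build_sim_cohort(small_config(n = 120, seed = 17))
  db2 <- sim$db
  # delete every record after each patient's index; covariates must not move
  truth <- attr(sim$db, "truth")
  idx_of <- function(ids) truth$index_day[match(ids, truth$id)]
  for (tb in c("diagnoses", "dispensings", "outcomes")) {
    keep <- db2[[tb]]$day <= idx_of(db2[[tb]]$id)
    db2[[tb]] <- db2[[tb]][keep, , drop = FALSE]
  }
  cand <- find_initiators(sim$db, sim$spec)
  cov1 <- assemble_covariates(sim$db, cand, sim$spec)
  cov2 <- assemble_covariates(db2, cand, sim$spec)
  expect_equal(cov1, cov2, ignore_attr = TRUE)
})

test_that("cohort construction is order-independent in the input rows", {
  sim <- build_sim_cohort(small_config(n = 80, seed = 23))
  db2 <- sim$db
  for (tb in names(db2)) {
    db2[[tb]] <- db2[[tb]][withr::with_seed(1, sample(nrow(db2[[tb]]))), ,
                           drop = FALSE]
    rownames(db2[[tb]]) <- NULL
  }
  c1 <- build_cohort(sim$db, sim$spec)
  c2 <- build_cohort(db2, sim$spec)
  c2 <- c2[match(c1$id, c2$id), ]
  rownames(c2) <- NULL
  expect_equal(c1, c2, ignore_attr = TRUE)
})
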