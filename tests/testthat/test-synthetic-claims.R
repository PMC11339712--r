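# Generator: config validation, determinism, structural invariants, and the
# Monte-Carlo counterfactual oracle.

test_that("invalid configurations are rejected with the field named", {
  expect_error(dgp_config(n_patients = 0), "n_patients")
  expect_error(dgp_config(covariates = list(cad = 1.2)), "covariates\\$cad")
  expect_error(dgp_config(censoring = list(prob = -0.1)), "censoring\\$prob")
  expect_error(dgp_config(duration = list(stop_prob = c(colchicine = 0.5))),
               "stop_prob")
  expect_error(dgp_config(strategy_effect = c(mace = 0.9)), "strategy_effect")
})

zero_hazard_cfg <- function(n = 200, seed = 4) {
  dgp_config(
    n_patients = n, seed = seed,
    hazards = list(mace = list(intercept = -Inf),
                   male = list(intercept = -Inf),
                   death = list(intercept = -Inf)),
    censoring = list(prob = 0)
  )
}

test_that("zero hazards and zero censoring give empty outcome and death tables", {
  db <- simulate_cohort(zero_hazard_cfg())
  expect_equal(nrow(db$deaths), 0)
  expect_equal(nrow(db$outcomes[db$outcomes$day >
                                  attr(db, "truth")$index_day[
                                    match(db$outcomes$id,
                                          attr(db, "truth")$id)], ]), 0)
  # everyone survives enrolled to administrative end
  expect_true(all(db$enrollment$end_day == zero_hazard_cfg()$admin_end))
})

test_that("same config and seed give byte-identical databases", {
  cfg <- small_config(n = 150, seed = 77)
  db1 <- simulate_cohort(cfg)
  db2 <- simulate_cohort(cfg)
  expect_identical(db1, db2)
  db3 <- simulate_cohort(small_config(n = 150, seed = 78))
  expect_false(identical(db1, db3))
})

test_that("simulated databases satisfy the structural invariants", {
  db <- simulate_cohort(small_config(n = 250, seed = 9))
  expect_silent(validate_claims_db(db))
  truth <- attr(db, "truth")
  # every patient has gout and PAD diagnoses before the ULT initiation day
  for (ct in c("gout", "PAD")) {
    dx <- db$diagnoses[db$diagnoses$category == ct, ]
    first <- tapply(dx$day, dx$id, min)
    expect_true(all(first[as.character(truth$id)] < truth$index_day))
  }
  # the initial prophylaxis course is abutting 30-day dispensings from the
  # index until the sampled discontinuation interval
  disp <- db$dispensings[db$dispensings$drug_class %in%
                           c("colchicine", "NSAID"), ]
  pick <- which(truth$stop_interval > 2)[1]
  one <- disp[disp$id == truth$id[pick] &
                disp$day < truth$index_day[pick] +
                  30 * truth$stop_interval[pick], ]
  one <- one[order(one$day), ]
  expect_equal(nrow(one), truth$stop_interval[pick])
  expect_true(all(diff(one$day) == 30))
})

test_that("covariate-free treatment model recovers the configured share", {
  p0 <- 0.56
  cfg <- dgp_config(n_patients = 10000, seed = 21,
                    treatment = list(intercept = qlogis(p0),
                                     coefs = numeric(0)))
  db <- simulate_cohort(cfg)
  share <- mean(attr(db, "truth")$arm == "colchicine")
  se <- sqrt(p0 * (1 - p0) / 10000)
  expect_lt(abs(share - p0), 3 * se)
})

test_that("oracle rejects unknown strategies and zero hazards give zero risk", {
  cfg <- zero_hazard_cfg(50)
  expect_error(simulate_counterfactual_risks(cfg, "no-such-strategy", 100, 1),
               "unknown strategy")
  tr <- simulate_counterfactual_risks(cfg, "always-colchicine", 2000, 1)
  expect_true(all(tr$true_risk == 0))
  expect_true(all(tr$mc_se > 0))
})

test_that("oracle matches the closed form for a constant covariate-free hazard", {
  cfg <- dgp_config(
    n_patients = 50, seed = 2,
    hazards = list(
      mace = list(intercept = qlogis(0.01), coefs = numeric(0),
                  steroid_logit = 0),
      male = list(intercept = -Inf, coefs = numeric(0)),
      death = list(intercept = -Inf, coefs = numeric(0))
    ),
    strategy_effect = c(mace = 1, male = 1, death = 1)
  )
  tr <- simulate_counterfactual_risks(cfg, "always-NSAID", n_mc = 60000,
                                      seed = 3, horizon = 720)
  expected <- 1 - 0.99^24
  expect_lt(abs(tr$true_risk[["composite"]] - expected),
            3 * tr$mc_se[["composite"]])
  expect_equal(tr$true_risk[["composite"]], tr$true_risk[["mace"]])
})

test_that("null strategy effect gives equal counterfactual risks", {
  cfg <- fully_null_config(100, seed = 5)
  a <- simulate_counterfactual_risks(cfg, "always-colchicine", 40000, seed = 8)
  b <- simulate_counterfactual_risks(cfg, "always-NSAID", 40000, seed = 9)
  se <- sqrt(a$mc_se[["composite"]]^2 + b$mc_se[["composite"]]^2)
  expect_lt(abs(a$true_risk[["composite"]] - b$true_risk[["composite"]]),
            3 * se)
})

test_that("the confounding knob separates crude contrasts from the oracle", {
  # covariates push both treatment choice and the hazards, so the crude
  # risk difference between observed arms is biased relative to the true
  # initiation contrast
  cfg <- dgp_config(n_patients = 10000, seed = 31)
  sim <- build_sim_cohort(cfg)
  cu <- weighted_km(sim$cohort, NULL, outcome_definition("composite"), 730)
  crude_rd <- risk_at(cu$colchicine, 730) - risk_at(cu$NSAID, 730)
  a <- simulate_counterfactual_risks(cfg, "initiate-colchicine", 60000,
                                     seed = 11, horizon = 730)
  b <- simulate_counterfactual_risks(cfg, "initiate-NSAID", 60000,
                                     seed = 12, horizon = 730)
  true_rd <- a$true_risk[["composite"]] - b$true_risk[["composite"]]
  se <- sqrt(a$mc_se[["composite"]]^2 + b$mc_se[["composite"]]^2)
  expect_gt(abs(crude_rd - true_rd), 3 * se)
})

test_that("claims databases round-trip through CSV files", {
  db <- simulate_cohort(small_config(n = 60, seed = 13))
  dir <- withr::local_tempdir()
  write_claims_db(db, dir)
  expect_setequal(list.files(dir),
                  paste0(c("patients", "enrollment", "diagnoses",
                           "dispensings", "outcomes", "deaths"), ".csv"))
  db2 <- read_claims_db(dir)
  for (nm in names(db2)) {
    expect_equal(db2[[nm]], db[[nm]], ignore_attr = TRUE)
  }
})
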