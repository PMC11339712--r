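# Baseline covariate dictionary shared by the generator, the cohort builder,
# the propensity/censoring models and the balance diagnostics.
#
# type:
#   binary      - 0/1 indicator
#   continuous  - standardized mean difference uses the pooled unweighted SD
#   count       - treated as continuous for balance, linear in models
#   categorical - expanded to indicators (one balance row per level)

#' Baseline covariate dictionary
#'
#' The covariate set used to emulate baseline randomization: demographics,
#' cardiovascular and renal comorbidity, gout and PAD severity, co-medication,
#' calendar time and enrolment history. Categorical covariates are expanded to
#' indicator columns in model designs; continuous covariates enter linearly.
#'
#' @return A data.frame with columns `name` and `type`
#'   (binary / continuous / count / categorical).
#' @export
trial_covariates <- function() {
  data.frame(
    name = c(
      "age", "sex_male", "race_nonwhite", "obesity", "cad", "cerebrovascular",
      "heart_failure", "afib", "ckd13", "copd", "diabetes", "insulin",
      "antihtn_count", "beta_blocker", "statin", "antiplatelet", "cilostazol",
      "anticoagulation", "prior_male", "prior_mace", "rest_pain", "tissue_loss",
      "elixhauser", "calendar_time", "enrolment_time", "gout_encounters",
      "febuxostat", "prior_steroid"
    ),
    type = c(
      "continuous", "binary", "binary", "binary", "binary", "binary",
      "binary", "binary", "binary", "binary", "binary", "binary",
      "categorical", "binary", "binary", "binary", "binary",
      "binary", "binary", "binary", "binary", "binary",
      "continuous", "continuous", "continuous", "count",
      "binary", "binary"
    ),
    stringsAsFactors = FALSE
  )
}

# Diagnosis categories recognised in the diagnoses table.
DX_CATEGORIES <- c(
  "PAD", "gout", "CAD", "HF", "AF", "CKD1-3", "CKD4-5/ESKD", "COPD",
  "diabetes", "hypertension", "hepatic_failure", "obesity", "cerebrovascular",
  "rest_pain", "tissue_loss", "encounter"
)

# Drug classes recognised in the dispensings table.
DRUG_CLASSES <- c(
  "ULT_allopurinol", "ULT_febuxostat", "colchicine", "NSAID", "steroid",
  "statin", "beta_blocker", "antiplatelet", "anticoagulant", "cilostazol",
  "insulin", "antihypertensive_1", "antihypertensive_2", "antihypertensive_3"
)

# Right-hand side of the baseline covariate model design, as a formula string.
covariate_formula_rhs <- function(covariates = trial_covariates()) {
  terms <- ifelse(
    covariates$type == "categorical",
    sprintf("factor(%s)", covariates$name),
    covariates$name
  )
  paste(terms, collapse = " + ")
}
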