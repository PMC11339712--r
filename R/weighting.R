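# Baseline-randomization emulation: propensity model, stabilized
# inverse-probability-of-treatment weights, truncation, balance diagnostics.

ps_design <- function(cohort, covariates = trial_covariates()) {
  miss <- setdiff(covariates$name, names(cohort))
  if (length(miss)) {
    stop("cohort is missing covariates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rhs <- covariate_formula_rhs(covariates)
  stats::as.formula(paste("treated ~", rhs))
}

#' Fit the treatment propensity model
#'
#' Maximum-likelihood logistic regression of the colchicine-arm indicator on
#' main effects of every baseline covariate (categorical covariates expanded
#' to indicators). Constant columns are dropped with a warning; separation or
#' non-convergence is an error naming the offending covariates.
#'
#' @param cohort a `trial_cohort` with covariates and an `arm` column.
#' @param covariates covariate dictionary (default [trial_covariates()]).
#' @return A `propensity_model`: the glm fit plus per-patient fitted
#'   probabilities of the colchicine arm.
#' @export
fit_propensity <- function(cohort, covariates = trial_covariates()) {
  if (length(unique(cohort$arm)) < 2 || min(table(cohort$arm)) < 2) {
    stop("need at least 2 patients in each arm to fit the propensity model",
         call. = FALSE)
  }
  keep <- vapply(covariates$name, function(nm) {
    length(unique(cohort[[nm]])) > 1
  }, logical(1))
  if (any(!keep)) {
    warning("dropping constant covariates: ",
            paste(covariates$name[!keep], collapse = ", "), call. = FALSE)
    covariates <- covariates[keep, , drop = FALSE]
  }
  dat <- cohort
  dat$treated <- as.integer(dat$arm == "colchicine")
  # convergence and positivity are checked explicitly below, which replaces
  # glm.fit's warnings
  fit <- suppressWarnings(stats::glm(ps_design(dat, covariates), data = dat,
                                     family = stats::binomial()))
  p <- as.numeric(stats::fitted(fit))
  if (!fit$converged || any(p < 1e-8) || any(p > 1 - 1e-8)) {
    cf <- stats::coef(fit)
    bad <- names(cf)[!is.na(cf) & abs(cf) > 10]
    stop("propensity model failed to converge (possible separation); ",
         "suspect covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(fit = fit, fitted = p, coefficients = stats::coef(fit),
         converged = fit$converged, covariates = covariates),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> %d patients, %d coefficients, converged: %s\n",
              length(x$fitted), length(x$coefficients), x$converged))
  invisible(x)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Weight = P(arm)/p for colchicine patients and (1 - P(arm))/(1 - p) for
#' NSAID patients, where P(arm) is the marginal colchicine share and p the
#' fitted probability of colchicine. Mean stabilized weight is approximately
#' 1 in large samples.
#'
#' @param model a `propensity_model`.
#' @param arms character vector of observed arms, aligned with the model.
#' @return A `weight_set` with elements `weight` (stabilized), `weight_raw`
#'   (pre-truncation copy), `ps`, `truncation_percentile` (NA until
#'   [truncate_weights()] is applied).
#' @export
stabilized_weights <- function(model, arms) {
  p <- model$fitted
  if (length(arms) != length(p)) {
    stop("arms must align with the fitted propensity model", call. = FALSE)
  }
  if (any(p <= 0) || any(p >= 1)) {
    stop("fitted probability of 0 or 1: positivity violation", call. = FALSE)
  }
  treated <- arms == "colchicine"
  marg <- mean(treated)
  w <- ifelse(treated, marg / p, (1 - marg) / (1 - p))
  structure(
    list(weight = w, weight_raw = w, ps = p,
         truncation_percentile = NA_real_),
    class = "weight_set"
  )
}

#' Truncate stabilized weights at an upper percentile
#'
#' Weights above the pooled (both-arm) empirical percentile are set to that
#' percentile; smaller weights are untouched. Monotone and idempotent.
#'
#' @param weights a `weight_set`.
#' @param percentile upper truncation percentile in (0, 100] (default 99).
#' @return The truncated `weight_set`; `weight_raw` keeps the pre-truncation
#'   values.
#' @export
truncate_weights <- function(weights, percentile = 99) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100) {
    stop("percentile must be in (0, 100]", call. = FALSE)
  }
  cap <- stats::quantile(weights$weight, percentile / 100, names = FALSE,
                         type = 7)
  weights$weight <- pmin(weights$weight, cap)
  weights$truncation_percentile <- percentile
  weights
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set> n=%d, mean=%.3f, range [%.3f, %.3f]",
              length(x$weight), mean(x$weight), min(x$weight), max(x$weight)))
  if (!is.na(x$truncation_percentile)) {
    cat(sprintf(", truncated at p%g", x$truncation_percentile))
  }
  cat("\n")
  invisible(x)
}

weighted_mean_sd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  c(mean = m, sd = sqrt(v))
}

#' Covariate balance before and after weighting
#'
#' For categorical/binary covariates the balance measure is the absolute
#' difference in (weighted) proportions; for continuous covariates the
#' absolute mean difference divided by the pooled unweighted standard
#' deviation `sqrt((s1^2 + s2^2)/2)` (the same denominator pre- and
#' post-weighting, so the two columns are comparable). Differences above 0.10
#' are flagged as residual imbalance. Categorical covariates contribute one
#' row per level.
#'
#' @param cohort a `trial_cohort` (or any data.frame with `arm` and the
#'   requested covariate columns).
#' @param weights a `weight_set`, or a numeric vector of weights, or NULL for
#'   unweighted-only diagnostics.
#' @param covariates covariate dictionary; rows whose `name` is absent from
#'   `cohort` are skipped.
#' @return A `balance_table` data.frame with unweighted and weighted arm
#'   means, differences, and imbalance flags.
#' @export
balance_table <- function(cohort, weights = NULL,
                          covariates = trial_covariates()) {
  w <- if (is.null(weights)) {
    rep(1, nrow(cohort))
  } else if (inherits(weights, "weight_set")) {
    weights$weight
  } else {
    weights
  }
  if (length(w) != nrow(cohort)) {
    stop("weights are not aligned to the cohort", call. = FALSE)
  }
  covariates <- covariates[covariates$name %in% names(cohort), , drop = FALSE]
  t_idx <- cohort$arm == "colchicine"

  rows <- list()
  for (i in seq_len(nrow(covariates))) {
    nm <- covariates$name[i]
    ty <- covariates$type[i]
    if (ty == "categorical") {
      lvls <- sort(unique(cohort[[nm]]))
      vars <- lapply(lvls, function(l) as.numeric(cohort[[nm]] == l))
      labs <- paste0(nm, "_", lvls)
      types <- rep("binary", length(lvls))
    } else {
      vars <- list(as.numeric(cohort[[nm]]))
      labs <- nm
      types <- ty
    }
    for (j in seq_along(vars)) {
      x <- vars[[j]]
      u1 <- weighted_mean_sd(x[t_idx], rep(1, sum(t_idx)))
      u0 <- weighted_mean_sd(x[!t_idx], rep(1, sum(!t_idx)))
      w1 <- weighted_mean_sd(x[t_idx], w[t_idx])
      w0 <- weighted_mean_sd(x[!t_idx], w[!t_idx])
      if (types[j] %in% c("continuous", "count")) {
        pooled_sd <- sqrt((u1[["sd"]]^2 + u0[["sd"]]^2) / 2)
        zero_sd <- pooled_sd == 0
        denom <- if (zero_sd) 1 else pooled_sd
      } else {
        zero_sd <- FALSE
        denom <- 1
      }
      d_unw <- abs(u1[["mean"]] - u0[["mean"]]) / denom
      d_w <- abs(w1[["mean"]] - w0[["mean"]]) / denom
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = labs[j], type = types[j],
        mean_treated = u1[["mean"]], mean_control = u0[["mean"]],
        wmean_treated = w1[["mean"]], wmean_control = w0[["mean"]],
        diff_unweighted = d_unw, diff_weighted = d_w,
        flag_unweighted = d_unw > 0.10, flag_weighted = d_w > 0.10,
        zero_sd = zero_sd,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("balance_table", "data.frame")
  out
}
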