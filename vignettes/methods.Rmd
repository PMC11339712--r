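---
title: "Methods: emulating initiation and duration trials of colchicine prophylaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating initiation and duration trials of colchicine prophylaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tteclaims)
```

# The scientific setting

Colchicine reduces major adverse cardiovascular events (MACE) in chronic
coronary disease, but its effect in lower-extremity peripheral artery
disease (PAD) is unknown. In patients with comorbid gout and PAD, the start
of urate-lowering therapy forces a prophylaxis choice — colchicine or an
NSAID — creating a natural active-comparator contrast at a shared inciting
event. This package emulates the two randomized trials that prescribing
fork supports:

1. an **initiation trial** (colchicine vs. NSAID at urate-lowering-therapy
   start), and
2. a **duration trial** (colchicine daily indefinitely vs. daily for 90
   days then stop).

The primary outcome is the 2-year composite of major adverse limb events
(MALE), MACE, and all-cause death. Follow-up runs from the index
dispensing to the outcome, plan disenrollment, or the administrative study
close, whichever is first.

# Cohort construction

A *new user* is a patient whose first urate-lowering dispensing has no
urate-lowering, colchicine, or NSAID dispensing in the preceding 183 days,
paired with a colchicine or NSAID dispensing within a **pairing window**
(default 14 days; the enrolment event itself does not pin down how tightly
the prophylaxis must follow the urate-lowering claim, so the window is a
configurable design choice). Patients dispensed both prophylaxis classes
inside the window have no well-defined arm and are excluded.

Eligibility then requires: index inside the study window; continuous
enrollment over the 183-day lookback; at least one diagnosis-table record
in the lookback (the operationalization of "uses the health system"); age
above 66 years at index; PAD and gout diagnoses on or before the index;
and no advanced kidney disease or hepatic failure in the lookback. Drops
are attributed to the *first* failing criterion in that order, giving a
deterministic attrition table; `candidates = eligible + sum(drops)` always
holds.

Baseline covariates (the `trial_covariates()` dictionary: demographics,
cardiovascular/renal/pulmonary comorbidity, PAD and gout severity,
co-medication, an Elixhauser score carried as a numeric covariate,
calendar time and enrolment history in 30-day blocks) are assembled
strictly from the lookback window, except demographics and the time
covariates, which use the full record. A property test verifies that
deleting all post-index records leaves every covariate unchanged.

# Trial 1: stabilized IPTW + weighted Kaplan–Meier

The propensity model is a maximum-likelihood logistic regression of the
colchicine indicator on main effects of all baseline covariates
(categorical covariates expanded to indicators; no interactions).
Stabilized weights are `P(A=a)/P(A=a|X)`, truncated at the pooled
(both-arm, one-sided upper) empirical 99th percentile — truncation laterality
and pooling are design choices; the convention here keeps the weighted
pseudo-population size near the observed size per arm.

Risks are estimated with a hand-implemented weighted product-limit
estimator because the required competing-risk convention is non-standard:
in the MALE-only and MACE-only analyses, **death neither censors nor
counts** — the dead stay in the risk set, contributing weight but no
events, through the horizon. The resulting quantity is a total-effect
cumulative incidence. On tied days, events precede censorings. With unit
weights and no competing flag the estimator agrees with
`survival::survfit` to 1e-12 (asserted in the tests, which is also why
`survival` is only a test dependency).

Balance diagnostics report the absolute difference in weighted proportions
(categorical) or the absolute mean difference over the pooled *unweighted*
standard deviation `sqrt((s1^2+s2^2)/2)` (continuous) — the same
denominator pre- and post-weighting so the two columns are comparable —
with 0.10 as the conventional imbalance flag.

Effect measures are the risk difference, risk ratio, and NNT/NNH (the
rounded inverse of the absolute risk difference, labelled by sign).
Display rounding is half-away-from-zero (`round_half_up()`), which is the
rule that reproduces the published tables' arithmetic (e.g. `1/0.054`
printed as 19).

# Trial 2: clone–censor–weight

Every Trial-1-eligible patient — not only colchicine initiators — is
duplicated into both strategy arms (the ambiguity of which population to
clone is resolved in favour of all-eligible, with `clone_scope =
"colchicine"` exposed as the alternative). Follow-up is discretized into
30-day intervals `[30k, 30(k+1))`; a 2-year read-off therefore uses 720
days (24 intervals), since 730 is not on the grid.

**On-treatment state** comes from dispensing coverage: consecutive
colchicine dispensings whose prescribed durations abut, with gaps up to a
**grace period** (default 30 days, configurable to 0) bridged. Grace
extends an initiated course; it never defers the day-0 requirement to
initiate. The long-term clone deviates at the first interval without
coverage; the short-term clone deviates at the first uncovered interval
before day 90 (both protocols demand treatment there, so an early stop
censors both clones) or at the interval of the first colchicine dispensing
at/after day `90 + grace`. Events in the deviation interval count only if
the event day does not exceed the deviation day, ties going to the event —
the same precedence rule as the Kaplan–Meier side. Protocol cannot be
violated after death, and dead clones stay in the table (frozen weight, no
events) for the competing-risk outcomes.

**Censoring weights.** Remaining-uncensored probabilities are fitted per
arm as pooled logistic regressions, in two blocks. Interval 0 — where the
only possible deviation is the baseline treatment decision itself — gets a
covariate-only model, the analogue of the baseline propensity score.
Intervals 1+ — where deviation is an adherence process — get the baseline
covariates plus the time-varying steroid indicator (the gout-flare proxy)
and cubic time. The split matters: pooling interval 0 with the rest forces
the strong covariate-dependence of the initial treatment choice onto late
intervals where deviation is nearly covariate-free, which distorts the
late-interval weights; the split removed exactly that distortion in the
null-calibration experiments the acceptance tests encode. Numerators are
intercept-only (interval 0) and cubic-time (intervals 1+); cumulative
ratios are truncated at the pooled 99th percentile across person-intervals.
Near-deterministic deviation cells (e.g. never-initiators at interval 0)
legitimately push fitted probabilities toward 0/1; stabilization plus
truncation bound the resulting weights, so those fits are not treated as
errors as long as the IRLS iterations converge.

**Outcome model.** A weighted pooled logistic model of the event indicator
on arm, `k`, `k^2`, `k^3`, and `arm:k` (one arm-time interaction by
default; a saturated per-interval time variant exists and reproduces the
empirical interval hazards exactly, which pins the plumbing to the
discretized Kaplan–Meier complement). Weighted fits use `quasibinomial` to
accept non-integer weighted responses; coefficients equal the binomial
weighted MLE. Standardized risk is `1 - prod(1 - h_k)` per arm on the
30-day grid.

# Inference

Percentile bootstrap, resampling *patients* (before cloning, so the two
clones of a patient always travel together), preserving cohort size, and
refitting every model — propensity, censoring, outcome — inside each
resample, since the weights are estimated quantities. Interval endpoints
are order-statistic (inverse-ECDF) percentiles: the `ceiling(a*B)`-th order
statistic, which makes the fixture arithmetic exact. Per-resample RNG
streams are derived from the root seed by resample index, so any resample
is reproducible in isolation. Resamples where a model fails to converge
are excluded and counted; more than 10% failures is an error.

# The synthetic claims generator

`dgp_config()` defines a complete data-generating process on integer days:

* **Baseline covariates** drawn independently with prevalences and moments
  matched to the published cohort (mean age 77 (SD 6.8), 54% coronary
  disease, Elixhauser mean 4.9 (SD 2.9), ...). The real joint distribution
  is unknown, so no claim of joint fidelity is made — only the margins and
  the induced imbalance pattern.
* **Treatment assignment**: logistic in atrial fibrillation, heart
  failure, anticoagulation, Elixhauser, age, prior steroid use and
  enrolment time, calibrated once so the *unweighted* arm imbalances
  reproduce the published pattern (five covariates above the 0.10
  threshold, Elixhauser ~0.22, atrial fibrillation ~0.15) and the
  colchicine share is ~55%.
* **Duration**: per-interval stop probabilities (0.12 colchicine, 0.22
  NSAID) give mean first-course durations near the published 247 and 137
  days; a restart probability (0.05/interval) makes use intermittent, as
  dispensing histories in claims are. Both transitions shift with
  current-interval steroid use.
* **Flares** are represented solely as steroid dispensings (the proxy used
  for the time-varying covariate): base 5% per interval, higher after
  discontinuation and for baseline steroid users — which makes steroid use
  a genuine time-varying confounder of adherence.
* **Outcomes**: per-interval logistic hazards for MACE, MALE and death in
  baseline covariates, current steroid use, and interval index, with
  intercepts set so the 2-year composite is roughly 30% at the covariate
  means (population-average risks land somewhat higher, ~35%, because the
  hazards are convex in the covariates). Colchicine exposure multiplies
  hazards by `strategy_effect` (default 0.9 for MACE and MALE, 1.0 for
  death, consistent with the modest published contrast).
* **Censoring**: 0.5%/interval disenrollment plus the administrative close
  of a ~12.5-year study window; late enrollees are admin-censored before 2
  years, as in the real design.

Day 0 of a patient's follow-up is the index date; all interval logic uses
half-open 30-day blocks. Identical `(config, seed)` pairs are byte-identical;
independent streams are derived per generation stage from the root seed.

The **counterfactual oracle** reruns the follow-up engine with treatment
forced: `always-colchicine`/`colchicine-indefinite`, `always-NSAID`, and
`colchicine-90-days-then-stop` disable the discontinuation process
entirely, while `initiate-colchicine`/`initiate-NSAID` keep natural
adherence — the latter pair exists because Trial 1's weighted Kaplan–Meier
targets an initiation (intention-to-treat analogue) contrast, which under
real-world discontinuation is *not* the always-on contrast. Oracle risks
are Monte-Carlo proportions with binomial standard errors (Jeffreys-adjusted
at the boundary).

What the generator does **not** emulate: real ICD/CPT vocabularies, claim
reimbursement structure, correlated covariates, dose information,
measurement error in diagnoses, informative disenrollment, or calendar
trends in hazards. Passing tests therefore demonstrate the estimators'
statistical correctness under a known, well-specified world — not
robustness to the misspecifications real claims data carry.

# Verification design and problem sizes

The test suite works at three levels:

* **Exact arithmetic**: the published tables' NNT/NNH, risk-ratio and
  mean-difference values re-derived from the printed risks, differences
  and counts.
* **Oracle equivalence**: the weighted product-limit estimator vs.
  `survival::survfit` (1e-12, 20-patient fixtures); the saturated-time
  pooled logistic risk vs. the discretized KM complement; hand-computed
  weighted product limits and cumulative weight products on 5-row
  fixtures.
* **Statistical properties** at sizes chosen to balance Monte-Carlo
  resolution against suite runtime: Trial 1 parameter recovery over 200
  cohorts of n = 2000 (weighted RD within 3 combined Monte-Carlo SEs of
  the oracle initiation contrast, crude RD outside it); the immortal-time
  demonstration over 100 replicates of n = 5000 under a fully null
  generator (no colchicine effect, no flare pathway into the hazards, so
  all strategies share one true risk — the naive duration grouping is
  significantly protective-looking while the clone-censor-weight mean is
  within 3 Monte-Carlo SEs of zero); and 95% bootstrap coverage between
  90% and 99% over 100 replicates of n = 1000 with 100 resamples each.

The fully null configuration zeroes the steroid-to-hazard coefficients
because with them active the two duration strategies genuinely differ
(stopping raises flare rates, flares raise hazards), so the strategy
contrast would not be null even with a null drug effect — a useful
reminder that "no treatment effect" and "no strategy contrast" are
different statements.

# Numerical and degenerate-input conventions

* Probabilities fitted at 0 or 1 in the propensity model are positivity
  errors; constant covariates are dropped with a warning.
* Arms or blocks with no deviations degenerate censoring probabilities to
  1 with a message rather than failing.
* `truncate_weights` is monotone and idempotent; percentile 100 is the
  identity.
* Zero pooled SD in a continuous balance row is flagged and reported
  unstandardized.
* Horizons not on the 30-day grid are an error for the discretized
  estimator, and the oracle accepts arbitrary day horizons.
* Undefined effect measures (zero risk difference, zero control risk) are
  flagged, never thrown.

# Known limitations

The Trial 2 estimand rests on the minority of patients with long
colchicine courses; at the published study size its sampling distribution
is wide and single datasets can produce extreme draws — the bootstrap
intervals reflect this honestly, and the acceptance script averages point
estimates over replicate databases for stable reporting. The censoring
models assume the measured covariates capture deviation selection
(adherence here depends on steroid use and baseline covariates by
construction; real adherence does not oblige). The per-protocol variant of
Trial 1 is not implemented because the deviation definition for simple
initiation arms is unspecified; the intention-to-treat analogue is the
supported Trial 1 analysis.
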