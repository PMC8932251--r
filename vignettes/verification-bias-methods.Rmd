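---
title: "Adjusting screening-test accuracy for verification bias: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting screening-test accuracy for verification bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veribias)
```

## The problem

In a screening study, K binary tests are applied to every participant, and
the definitive reference standard (for example a biopsy) is applied only to
those the tests flag: under the usual *any-positive* rule, a participant is
referred for verification when at least one test is positive. Disease
status is therefore observed mostly in screen-positives. The naive
"complete-case" analysis — computing sensitivity, specificity, PPV and NPV
from verified participants only — is biased: screen-negative participants,
who are predominantly non-diseased, are missing from the denominators, so
sensitivity is inflated and specificity deflated. This is verification
(work-up) bias.

Both corrections implemented here rest on the **missing-at-random (MAR)**
assumption: whether a participant is verified depends only on the observed
test results, never directly on the unobserved disease status. Under MAR,
within every one of the 2^K strata of test-result combinations,
`Pr(D | Q) = Pr(D | Q, V = 1)`: the disease prevalence seen among the
verified members of a stratum applies to its non-verified members too.

## Data model

`screening_data` is a participant-level data frame: K strictly 0/1 test
columns, a 0/1 `verified` flag, and `disease` that is `NA` exactly when
`verified == 0`. Three conventions worth stating:

* Records with any missing test result are excluded at ingest and counted;
  a test result that never happened cannot define a stratum.
* A disease value recorded for a non-verified participant is discarded with
  a warning rather than rejected: the estimand treats unverified status as
  missing by design, and a stray value is a data-entry artifact. An error
  would block ingest of otherwise usable files; silent acceptance would
  leak unverifiable outcomes into the analysis.
* Thresholding of continuous markers (e.g. a biomarker level against a
  clinical cutoff) is deliberately outside the core: `apply_thresholds()`
  is provided, but the estimators refuse non-binary input rather than
  guessing units.

Strata are enumerated in binary order with the first test as the most
significant bit, so tables and reports are byte-stable. Nothing is
hard-coded to three tests; all machinery runs over 2^K strata.

## The allocation (Begg–Greenes) estimator

`allocate_nonverified()` splits each stratum's non-verified count `n0(q)`
in proportion to the verified disease split of the same stratum:

    e_dis(q) = n0(q) * n_ver_dis(q) / n_ver(q)

The allocated counts are *expectations* and stay fractional throughout;
rounding happens only at display. Rounding earlier would break the exact
conservation `sum(all cells) = N`, which the test suite asserts to 1e-12.

`bg_accuracy()` then marginalizes: adjusted sensitivity for test j is the
sum of (observed + allocated) diseased counts over strata where test j is
positive, divided by the same sum over all strata — algebraically the
Bayes-theorem form `Pr(test+ | D) = Σ_q Pr(Q=q) Pr(D | Q=q, V=1)`
restricted to test-positive strata, with both probabilities estimated from
the data. The test suite checks the two routes agree to 1e-10 on a
thousand random tables, and that the estimator collapses *exactly* to the
complete-case one when everyone is verified.

**Identifiability.** The method needs every stratum that contains
non-verified participants to contain at least one verified participant.
The binding case in practice is the all-negative stratum: by design,
all-negative participants are not referred, so studies should verify a
small random audit of screen-negatives. `validate_for_begg_greenes()`
reports offending strata and flags the all-negative one specially;
`allocate_nonverified()` refuses to run and recommends multiple
imputation, which borrows strength across strata through the disease
model.

**Intervals.** Confidence intervals come from a participant-level
nonparametric bootstrap (`bg_bootstrap()`), resampling verified and
non-verified records together. Percentile intervals are the default, using
the (B+1)α order-statistic convention for the endpoints; a `basic`
variant is available. Default B = 1000. A resample can lose a stratum's
only verified anchor (in the motivating design, the single verified
all-negative participant); such replicates are invalid, and the default
policy redraws them (up to `100 * B` extra draws) while counting how many
were encountered — dropping them instead is available. Replicate draws are
consumed from one seeded generator in sequence, so a run is exactly
reproducible from its seed.

A known limitation, quantified in the package's own coverage study:
percentile intervals are first-order accurate, and for a skewed
proportion-like statistic with a small effective denominator (sensitivity
near 0.85 with ~200 diseased) their realized coverage at the nominal 95%
level is about 88% — the same regime in which Wald intervals dip.
Measures with large effective denominators (specificity, NPV) sit at
93–95%.

## Multiple imputation

`mi_estimate()` implements the six-step imputation algorithm:

1. Fit a logistic regression of disease status on the K test results,
   using verified participants only (main effects by default, matching a
   conditional-independence working model; `interaction_screen()` checks
   pairwise and three-way products by Wald tests at α = 0.05).
2. For every non-verified participant, compute the predicted disease
   probability by inverse logit and draw a 0/1 status by comparing one
   uniform variate to it.
3. Compute every accuracy measure on the completed cohort.
4. Repeat for m imputations (default m = 100).
5. The pooled point estimate is the mean over imputations.
6. Variances combine by Rubin's rules, `T = W + (1 + 1/m) B`, where `W` is
   the mean within-imputation variance and `B` the between-imputation
   sample variance.

The model is fitted **once** on the observed verified data and held fixed
across imputations — the algorithm's steps as stated, which is "improper"
multiple imputation in Rubin's terminology. A `proper = TRUE` switch adds
a draw of the coefficient vector from its asymptotic normal approximation
per imputation; it is off by default to keep the default analysis exactly
the stated algorithm.

**Variances and intervals.** The within-imputation variance of a
proportion is `p(1-p)/n` on that imputation's completed-data denominator
(denominators vary across imputations for sensitivity, specificity, PPV
and NPV, because disease counts are imputed). Boundary proportions are
clamped to `0.5/(n+1)` — the shrinkage point an intercept-only penalized
fit would give — so pooling never divides by zero. Intervals are Wilson
score intervals evaluated at an **effective sample size**
`n_eff = p̄(1-p̄)/T`, capped at the nominal denominator: the denominator at
which a binomial variance matches the total MI variance. This moment-match
is isolated in `effective_sample_size()` so an alternative
degrees-of-freedom construction can be swapped in without touching the
rest. Whether per-imputation variances should instead be completed-data
Wilson variances is a genuinely open choice; the Wald form was chosen as
the simplest one consistent with the Wilson/effective-n pooling target.
An imputation in which a measure's denominator is zero is excluded from
that measure's pooling with a logged count.

**Why Firth.** Screening cohorts have few events: with 16 events and 3
covariates, events-per-variable (EPV) is 5.3, well under the common
guideline of 10, and ML logit coefficients are biased away from zero in
that regime (and infinite under separation). `fit_firth()` maximizes
`loglik + 0.5 * log det(X'WX)` via the modified-score iteration (residual
`y - p` replaced by `y - p + h(0.5 - p)` with `h` the hat leverages) with
step-halving; the penalty removes the leading-order bias, vanishes as n
grows (the suite checks ML and Firth agree to < 0.01 at n = 10,000), and
always yields finite estimates. `epv_check()` computes EPV and recommends
the penalized path when it is low. Convergence: tolerance 1e-8 on the
penalized-score norm, max 100 iterations, up to 20 halvings per step —
standard Firth practice.

`fit_ml()` delegates to the stats IRLS fitter and adds a separation
diagnostic: coefficients beyond ±15 combined with either a non-vanished
score *or* fitted probabilities at the 0/1 boundary are reported as
non-converged with a separation flag. The boundary clause matters: on a
completely separated dataset the IRLS score can numerically vanish at
machine-boundary fitted probabilities, so a score criterion alone would
certify a divergent fit as converged.

## The simulator

`simulate_screening()` generates the study design the estimators assume:
true status Bernoulli(prevalence); tests conditionally independent given
status at the configured sensitivities/specificities (a latent-Gaussian
`latent_rho` knob can induce within-participant dependence for robustness
work); any-positive referral; then an independent withdrawal coin for
screen-positives and an audit coin for all-negatives. Verification
depends only on test results and exogenous coins, so MAR holds by
construction — and because the hidden truth is returned alongside (never
inside) the dataset, the suite can verify MAR empirically, demonstrate
the complete-case specificity deflation, check parameter recovery at
N = 100,000 within ±0.02, and run interval-coverage studies.

`simulate_prostagram_like()` freezes a fixture-scale configuration
emulating a population prostate-cancer screening cohort: N = 403, three
tests with operating points (0.87, 0.56, 0.37) sensitivity and
(0.79, 0.78, 0.92) specificity, prevalence 4.5%, withdrawal 9% (about 17
of ~180 screen-positives), audit 0.5% (about one all-negative
participant). These values put the expected verified fraction at ~42%.

What the simulator does *not* emulate: continuous marker distributions
(tests are generated directly as binaries), non-MAR verification (e.g.
clinicians referring on symptoms correlated with disease), imperfect
reference standards, and correlated withdrawal. Passing tests therefore
demonstrate correctness *under MAR with binary tests*, not robustness to
violations of those assumptions.

## Study-condition choices for the validation suite

The packaged cohort (`prostagram_fixture()`) pairs the published
non-verified stratum counts with a synthetic verified joint allocation
that reproduces every published complete-case marginal; the true verified
joint table was never published, so the adjusted estimates on this fixture
are illustrative rather than reproductions (the complete-case column and
structural counts are exact reproductions).

Simulation-based tests use: parameter recovery at N = 100,000 with a 10%
negative audit; method agreement (MI vs allocation) at N = 2,000 with
m = 100; and interval coverage over 500 datasets of N = 2,000 with
B = 200, prevalence 0.10, sensitivities (0.85, 0.60, 0.40), specificities
(0.75, 0.80, 0.90), 10% audit, 5% withdrawal — sizes chosen as a
realistic low-prevalence screening design with healthy denominators for
every measure.

## Degenerate inputs and tie-breaks

* Zero-denominator measures return `NA` with the rest of the report
  intact; `sensitivity()` and friends raise an error naming the measure.
* Exact (Clopper–Pearson) intervals require integer counts and refuse
  fractional ones; fractional (allocated or effective) denominators take
  the Wilson route, which is defined for any positive real denominator.
* The complete-case default interval is Clopper–Pearson; a Wilson switch
  exists because published reports mix conventions for marginal
  prevalences.
* Strata with neither verified nor non-verified members contribute
  nothing and are skipped silently.
* An empty input file with a valid header is a valid zero-record dataset.
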