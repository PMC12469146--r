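---
title: "Correcting partial verification bias by scaled inverse probability resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting partial verification bias by scaled inverse probability resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipw)
```

## The problem

A diagnostic accuracy study compares a binary index test $T$ against a
gold-standard disease status $D$ and reports sensitivity
$Sn = P(T{=}1 \mid D{=}1)$ and specificity $Sp = P(T{=}0 \mid D{=}0)$.
When the gold standard is invasive or expensive, clinicians verify mostly
the test-positive patients. If verification status $V$ depends on $T$, the
verified subsample is not a random sample: estimating $Sn$ and $Sp$ from
the verified patients alone (complete case analysis, CCA) inflates $Sn$
and deflates $Sp$. This distortion is partial verification bias (PVB).
Because the decision to verify depends only on the observed test result,
the missing $D$ values are missing at random (MAR) given $T$.

A subject-level dataset in this package is a tibble with columns `test`,
`disease` (NA exactly when unverified) and `verified`; see `pvb_data()`.

## Estimators

All methods condition on the binary test only.

* **FDA** (`estimate_fda`) — the benchmark on fully verified data.
* **CCA** (`estimate_cca`) — verified subjects only; biased under PVB.
  Its large-sample limit under verification probabilities
  $\lambda_t = P(V{=}1 \mid T{=}t)$ is
  $\lambda_1 Sn / (\lambda_1 Sn + \lambda_0 (1 - Sn))$ for sensitivity
  (and symmetrically for specificity), which the tests check at
  $n = 10^5$.
* **Begg–Greenes** (`estimate_bg`) — rewrites the accuracy measures
  through $P(D \mid T)$, estimated from verified subjects (valid under
  MAR), weighted by the fully observed test margin: with $s_t$ the size
  of test stratum $t$ and $d_t = \hat P(D{=}1 \mid T{=}t, V{=}1)$,
  $Sn = s_1 d_1 / (s_1 d_1 + s_0 d_0)$ and
  $Sp = s_0(1-d_0) / (s_1(1-d_1) + s_0(1-d_0))$.
* **IPWE** (`estimate_ipwe`) — Horvitz–Thompson weighting of the verified
  cross table by the inverse of the verification propensity
  $PS = \hat P(V{=}1 \mid T)$. For a binary test the propensity model is
  saturated, and IPWE is algebraically identical to Begg–Greenes; the
  test suite asserts this equality to machine precision on a thousand
  random datasets.
* **MI** (`estimate_mi`) — proper multiple imputation of the missing $D$
  from a logistic model of $D$ on $T$: one coefficient vector per
  imputation is drawn from the asymptotic normal of the verified-data
  fit, missing statuses are imputed as Bernoulli draws, estimates are
  pooled by averaging, and Rubin's rules give the interval.
* **IPB** (`estimate_ipb`) — weighted bootstrap of the verified subjects
  (resamples of size $n_1$) with probabilities proportional to $1/PS$.
* **SIPW** (`estimate_sipw`) — as IPB but each resample restores the full
  sample size $n$, so the output is a complete dataset whose distribution
  is corrected for the verification mechanism.
* **SIPW-B** (`estimate_sipwb`) — SIPW with the resampling mass first
  rebalanced between diseased and non-diseased subjects to a chosen
  control:case ratio, mimicking a case-control design.

### Weighting details

For verified subject $i$, $IPW_i = 1/PS_i$ and the scaled weight is
$SIPW_i = IPW_i / \sum_j IPW_j$ over verified subjects, so the weights
form a resampling distribution (they sum to one). The balanced variant
multiplies the diseased subjects' $IPW$ by the observed relative size
$n_{D=0}/n_{D=1}$ (counted among verified subjects), then by
$k/\text{rel\_size}$ with $k$ the control-to-case ratio of the summed
weights, and renormalizes over **all** verified subjects. The subscript
on the normalizing sum is ambiguous in narrative descriptions of this
scheme; normalizing over all verified subjects is the only reading under
which the weights sum to one, and it yields the exact identity
$\sum_{D=1} SIPW_i = 1/(1 + \text{rel\_size})$, asserted in the tests.
The class counts entering the rebalancing can only be taken among
verified subjects, since $D$ is unknown elsewhere.

Each candidate resample is screened: if its $T \times D$ table has an
empty cell the draw is rejected and repeated (the estimate would be
undefined). The rejection budget is 1000 redraws per resample, after
which the weights are effectively degenerate and an error is raised.

### How the resamples are drawn

The propensity model conditions on $T$ only and the rebalancing acts on
$D$, so every subject within one $(T, D)$ cell carries the same weight.
The cross table of a weighted resample of size $s$ is therefore exactly
$\text{Multinomial}(s, q)$ with $q$ the per-cell weight mass, and the
estimators draw tables directly (`stats::rmultinom`) instead of subject
indices. This is an exact distributional reduction, not an
approximation; the test suite verifies it against a brute-force
enumeration of all subject-level tuples of a small resample, and the
subject-level path remains available through `draw_valid_resample()`
for users who want restored datasets for downstream analyses.

### Propensity estimation

The logistic regression of $V$ on a single binary $T$ is saturated, so
the maximum-likelihood propensities are the stratum verification
proportions; `fit_propensity()` uses this closed form. A stratum that is
entirely verified or entirely unverified is perfect separation: the
weights are undefined and the function stops with guidance rather than
returning boundary propensities.

## The simulation engine

`simulate_complete()` draws $(T, D)$ jointly from the multinomial model
$\pi_1 = Sn\,p$, $\pi_2 = (1{-}Sn)\,p$, $\pi_3 = (1{-}Sp)(1{-}p)$,
$\pi_4 = Sp\,(1{-}p)$; `mask_mar()` applies Bernoulli verification with
$P(V{=}1\mid T{=}1) = 0.8$ and $P(V{=}1\mid T{=}0) = 0.4$ by default —
the canonical moderate-selection setting in the PVB simulation
literature, under which between roughly 45% and 64% of subjects are
verified depending on the accuracy pair (`expected_verification_rate()`
gives the analytic value). `simulate_pvb_pair()` redraws the pair until
both the complete table and the verified-only table have four nonzero
cells. Screening the verified table (not only the complete one) is an
interpretation: every estimator needs four nonzero verified cells, so
datasets failing it could not be analyzed by any method under study. The
retry budget is 10,000 draws; scenarios so extreme that no valid dataset
appears within it raise an error naming the scenario.

The default study grid (`default_grid()`) crosses prevalence
$p \in \{0.4, 0.1\}$ with six $(Sn, Sp)$ pairs and $n \in \{200, 1000\}$.
The generator emulates the multinomial/MAR mechanism only: real studies
have covariate-dependent verification, correlated test batteries and
imperfect gold standards, none of which appear here — passing tests
establish correctness under MAR with test-only selection, not robustness
beyond it.

## Performance metrics

`run_scenario()` simulates `B` screened dataset pairs and reports, per
method, the mean estimate, bias (mean − truth) and standard error. For
the direct estimators the SE is the between-replication standard
deviation. For the resampling estimators it is the standard deviation of
the *individual* valid-resample estimates pooled across replications
(computed exactly from per-replication means and within-replication
variances). The pooled convention tracks the spread a practitioner
faces when a single corrected resample is taken forward to downstream
analysis, and it is the dispersion measure under which the documented
precision ordering of the three resampling methods (IPB widest, then
SIPW, then SIPW-B for sensitivity) is a stable, reproducible fact; the
b-averaged point estimates, whose spread is essentially that of IPWE,
are still what the bias column uses.

Monte Carlo sizes follow the study design: `B = 500` replications,
`b = 1000` resamples, `m = 100` imputations. The test suite reproduces
the headline table cells at exactly these sizes and uses smaller sizes
(`B` of tens to a few hundred, `b` of a few hundred) for property-style
checks where only means matter — chosen so the whole suite stays a
few-minute run while keeping Monte Carlo noise well inside the asserted
tolerances.

## Confidence intervals

* `ci_wald()` — normal-approximation interval on the verified
  denominators (used for CCA).
* `ci_boot_percentile()` — nonparametric bootstrap of whole subject
  rows, so the missingness pattern is resampled with the data;
  replicates where the estimator fails are redrawn under a budget of
  `10 * R` draws. Quantiles use linear interpolation (R's default
  type 7), recorded in the output metadata since percentile dialects
  differ. Used for BG, IPWE, SIPW and SIPW-B; for BG this is a
  pragmatic method-agnostic choice — the correction's original
  closed-form variance is not implemented here.
* `ci_ipb_native()` — IPB's resamples are genuine bootstrap samples of
  the verified subset, so its interval is read off the stored
  per-resample estimates without extra work.
* `ci_rubin()` — Rubin's rules with Wald within-imputation variances and
  the standard degrees of freedom $(m-1)(1 + W/((1{+}1/m)B))^2$; when
  the between-imputation variance is zero the interval collapses to the
  Wald interval of a single completed dataset (a normal quantile is used
  since the df are unbounded there).

Intervals are truncated to $[0, 1]$. A percentile interval that fails
to contain the point estimate (possible with degenerate resamples) is
reported as-is with a warning, never silently clamped.

## Multiple imputation details

The disease-model fit augments the verified records with four weighted
pseudo-observations (both outcomes at $T = \bar T \pm 0.5\,\mathrm{sd}(T)$,
total weight 2), the standard perfect-prediction safeguard in MI
software. With sparse strata — low prevalence, few verified
test-negatives — this regularization materially affects the imputed
disease rates and is the difference between a mildly and a strongly
biased sensitivity estimate in the low-prevalence corner of the study
grid; with ample data its effect is negligible. Inputs with *exact*
separation (a verified stratum with only one disease class) still raise
an error pointing to BG/IPWE, whose estimates remain defined there. For
clinical analyses `analyze_clinical()` follows the convention of setting
$m$ to the rounded percentage of incomplete cases.

## Clinical fixtures

The two bundled datasets (`inst/extdata/*_synthetic.csv`) have the
margins of the classical hepatic-scintigraphy (650 patients, 344
verified) and diaphanography (900 patients, 88 verified) case studies.
Their cell counts are a reconstruction solved from those margins and the
reported uncorrected and corrected accuracy estimates, not the original
patient records — hence the `_synthetic` label. They exercise the
sparse-verification regime where the native IPB interval is visibly
wider than the bootstrap intervals of SIPW/SIPW-B.

## Reproducibility

All randomness flows through R's global RNG. The harness functions
(`run_scenario()`, `run_grid()`, `analyze_clinical()`, `pvb_correct()`)
accept a `seed`; `run_grid()` derives one sub-seed per scenario from the
master seed, so a grid run is reproducible end to end. Execution is
serial; per-repetition substreams for parallel execution are not
implemented.

## Known limitations

* Only a single binary test: no covariates in the propensity or disease
  models, no multi-category or continuous index tests.
* MAR only; verification driven by unobserved disease status (MNAR) is
  out of scope.
* After class rebalancing, prevalence-dependent quantities (PPV, NPV,
  accuracy) computed from an SIPW-B resample are invalid — the disease
  mix was deliberately altered. Use SIPW when restored data must keep
  the original prevalence.
* The resampling methods are computationally heavier than the
  closed-form corrections, and interval estimation for SIPW/SIPW-B
  multiplies that cost by the bootstrap replicate count.

## A worked example

```{r example, eval = FALSE}
set.seed(2026)
pair <- simulate_pvb_pair(n = 1000, p = 0.4, sn = 0.3, sp = 0.6)

tidy(pvb_correct(pair$pvb, "cca"))   # biased: Sn far above 0.3
tidy(pvb_correct(pair$pvb, "sipw", ci = "boot", R = 200))

res <- run_scenario(0.4, 0.3, 0.6, n = 1000,
                    methods = c("fda", "cca", "bg", "sipw"),
                    B = 100, b = 500, seed = 1)
autoplot(res, "bias")
```
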