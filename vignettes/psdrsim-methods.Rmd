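---
title: "Evaluating machine-learning propensity and disease risk scores with plasmode simulation and negative controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating machine-learning propensity and disease risk scores with plasmode simulation and negative controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observational treatment-effect estimation must remove confounding: sicker
patients are both more likely to receive treatment and more likely to
experience outcomes. Two balancing summaries dominate pharmacoepidemiology:
the **propensity score** (PS), $e(x) = P(T=1 \mid X=x)$, and the **disease
risk score** (DRS), $r(x) = P(Y=1 \mid X=x, T=0)$. Matching treated subjects
to untreated subjects with similar scores targets the average treatment
effect on the treated (ATT).

`psdrsim` evaluates how well four estimation methods — logistic regression
on a clinically chosen confounder list ("reference"), L1-penalised logistic
regression (LASSO), gradient-boosted trees (XgBoost) and a multi-layer
perceptron (MLP) — support PS and DRS matching, using two complementary
designs:

* a **real-world-like arm**: a cohort with 69 negative-control time-to-event
  outcomes (outcomes with no causal relation to treatment, so the true
  hazard ratio is 1). The fraction of 95% CIs containing the null
  (*coverage*) and the RMSE of the log-HR estimates measure residual bias;
* a **plasmode arm**: covariate rows are resampled with replacement from the
  cohort, and treatment and a rare binary outcome are simulated from
  logistic models with a known injected effect $\beta_t$, preserving the
  real covariate dependence while making the truth available. Relative bias
  $(\hat\beta_t - \beta_t)/\beta_t$ is the accuracy metric.

Because the motivating data (UK primary-care records) are confidential, the
package starts one step earlier: a **synthetic base cohort generator**
provides the substrate with the statistical features the analysis depends
on. Every stage is therefore runnable and testable from a single seed.

## The synthetic base cohort

`generate_base_cohort()` composes three generators.

**Covariates.** A single-factor latent Gaussian model: with factor
$F_i \sim N(0,1)$, noise $\epsilon_{ij} \sim N(0,1)$ and loading
$\sqrt{\rho}$ (config `latent_correlation`, default 0.2),
$X_{ij} = 1\{\sqrt{\rho} F_i + \sqrt{1-\rho}\,\epsilon_{ij} < \Phi^{-1}(p_j)\}$.
Marginal prevalences hit their targets $p_j$ exactly in expectation, and all
covariates are positively dependent — the qualitative signature of
comorbidity indicators. Prevalences are drawn log-uniformly in
`prevalence_range` (default 0.004–0.30), reproducing the long tail of rare
codes; one parameter controls dependence without a full copula. What this
does **not** emulate: categorical covariates (age bands, calendar year),
negative dependence, and block structure of real code hierarchies. Passing
tests therefore demonstrate correct machinery under exchangeable sparse
binary covariates, not performance on real claims data.

**Prescriptions.** Each subject initiates treatment with probability
$\mathrm{expit}(\alpha + w^\top x_i)$, with $\alpha$ calibrated by bisection
(`calibrate_intercept()`, achieved mean within $10^{-10}$ of the target) to
the configured exposure prevalence, default 0.26 — the scale of the
motivating cohort (163,597 users of 632,201 subjects). Initiators receive
1–4 prescriptions of 28–90 days with refill gaps drawn short (< 90 days,
80%) or long (90–365 days), so era construction sees both continuation and
re-initiation.

**Negative-control events.** Event times are exponential with subject rate
$h_0 \exp(\gamma^\top x_i)$, administratively censored at follow-up end;
by default each of the 69 outcomes loads on 10 random covariates with
$|\gamma| = \log 1.5$. Treatment appears nowhere, so the true HR is exactly
1 while covariate effects create confounding pressure. The exponential with
administrative censoring is the simplest hazard model in which that null is
exactly encodable. A separate *clinical reference outcome* with the same
construction stands in for the clinical endpoint that real analyses use to
pick confounders and fit DRS models; it is never analysed as a negative
control.

Day arithmetic is integer, half-open, with day 0 the study start — no
calendar logic.

## Cohort building

`build_eras()` applies the refill-gap rule: prescriptions of one subject
sorted by start are merged while the gap to the running era end is
**strictly less than** 90 days; a gap of exactly 90 starts a new era (the
literal reading of a "< 90-day refill gap"). `assign_exposure()` makes a
subject a user at their first era start (the index day); non-users carry no
index day — in matched analyses each control inherits the index day of its
treated subject (pseudo-index), anchoring follow-up comparably and avoiding
immortal time. `filter_covariates()` drops covariates with prevalence
$\le 0.004$ (boundary inclusive for exclusion), computed on the full source
population before any matching.

## Score models

All four methods share one contract: `(data, config) -> fitted_score_model`
with scores in $[0,1]$, so matching and evaluation are method-agnostic.
The reference method sees only its supplied confounder list; the
data-driven methods see every covariate. Hyperparameters are tuned by
exhaustive grid search minimising the mean Brier score over a fixed seeded
10-fold partition, ties broken by grid order; candidates that fail to fit
are logged with infinite Brier. Matching uses in-sample scores (fit on the
full data after tuning), standard PS practice; out-of-fold scores would be
a one-line change but are not the default because the evaluation design
already separates score estimation from effect estimation.

Default grids are small but exercise every tuned dimension: LASSO over 20
log-spaced penalties spanning $10^{-4}\lambda_{max}$ to $\lambda_{max}$;
XgBoost over rounds {100, 300} × depth {3, 6} × learning rate
{0.05, 0.1} × min child weight {1, 10} × subsample {0.7, 1.0}; the MLP —
a single-hidden-layer feedforward network (`nnet`), the standard R
formulation — over width {4, 16} × weight decay {0.01, 0.1} × epochs
{50, 150}, single-threaded with fixed initialisation seeds so results are
bit-reproducible. No oversampling is applied for the rare DRS outcome; the
rare-event behaviour of the data-driven DRS methods is part of what the
package measures.

Two DRS variants are implemented: the **full-cohort DRS** (outcome on
covariates and treatment over everyone, predicted with the treatment
feature forced to 0) — the default, as it is known to dominate the
alternative — and the **unexposed DRS** (fitted on untreated subjects only,
predicted for all).

## Matching and balance

`greedy_match()` is a deterministic pass-based greedy matcher with a
maximum ratio of 5 controls per treated subject and a caliper of 0.05 on
the probability scale (no SD-of-logit scaling; the caliper is interpreted
literally, and an SD-based caliper can be emulated by rescaling). Pass
$k$ gives every still-matchable treated subject its $k$-th control:
treated subjects are processed in descending score order (hardest first),
each taking its nearest available control within the caliper, with exact
distance ties resolved toward the lower-score neighbour in the
(score, position)-sorted control list. The pass structure prevents early
treated subjects from monopolising scarce controls; processing by
descending score is deterministic and favours the thinly supported tail.
The matcher's inner loop is compiled (Rcpp) and is verified in the test
suite against an independent brute-force R implementation of the same
written rules on 200 random instances, including tied scores and
with-replacement mode.

Balance uses the pooled two-proportion SMD for binary covariates,
$|p_1 - p_0| / \sqrt{(p_1(1-p_1)+p_0(1-p_0))/2}$, with $0/0$ defined as 0,
and the ASMD is the unweighted mean over covariates; 0.1 is drawn on every
balance figure as the conventional acceptability threshold. After-matching
balance counts each matched control once by default (the literal matched
sample). A matching-weights mode (controls weighted $1/k$ in a $1\!:\!k$
set) is provided because unweighted variable-ratio samples distort the ATT
covariate distribution: later passes accept systematically more distant
controls, so the unweighted matched sample — the literal analysis sample of
the motivating design — retains imbalance that the weighted or 1:1 view of
the same matches does not, and its matched Cox estimates inherit that
residual confounding. The analysis scripts' below-nominal null coverages
under covariate-driven negative-control events show exactly this pattern,
mirroring the depressed real-world coverages the design is known to
produce; the test suite's null-calibration check instead uses events
independent of the covariates, for which coverage is nominal regardless of
balance.

## Effect estimation and metrics

Cox models (Efron ties) with treatment as the only covariate estimate the
per-outcome log-HR on the matched sample; follow-up runs from the
(inherited) index day to event or censoring, subjects with events on or
before index are excluded, and an outcome with no events in either arm is
flagged non-estimable rather than failing the run — non-estimable outcomes
leave the coverage/RMSE denominators and their count is reported. The
matched-set structure is ignored by default (plain Cox, as in the
motivating design); stratified and robust-variance options exist. The
plasmode effect is the treatment coefficient of an intercept + treatment
logistic fit on the matched sample, which equals the closed-form 2×2
log-odds ratio — asserted to $10^{-6}$ in the tests.

Coverage is computed on the log scale (CI contains 0), making it invariant
to exponentiation conventions. RMSE defaults to the log-HR scale with
truth 0, $\sqrt{\mathrm{mean}(\hat\beta^2)}$; an HR-scale mode
($\sqrt{\mathrm{mean}((e^{\hat\beta}-1)^2)}$) is provided and the mode is
always recorded, because "RMSE of the estimated hazard ratio" is ambiguous.
Replicate summaries report mean ± 1.96 sd/√n intervals.

## Plasmode design choices

Roles default to association ranking — confounders are the covariates with
the largest product of absolute univariate log-odds associations with
exposure and outcome, instruments the strongest remaining exposure-only,
risk factors the strongest remaining outcome-only — mimicking "essential
covariates"; a random strategy exists for null experiments. Generating
coefficients are transferred from logistic fits of observed treatment and
of the clinical reference outcome on the role sets (ridge-stabilised on
separation), zeroed outside their role support, so instruments have exactly
zero direct outcome effect in the generator. The outcome intercept is
calibrated *conditional on the realised treatment vector*, so the marginal
outcome risk matches its target (default 0.0075) at the simulated
treatment mix. The injected effect defaults to $\beta_t = \log 2$:
any nonzero value supports the relative-bias metric and OR = 2 is
interpretable. Per-replicate seeds are a deterministic hash of (master
seed, replicate index), so replicates are independently reproducible and
parallelisable. Replicate count defaults to 100 and every summary records
the count actually used.

## Problem sizes and numerical choices

The shipped analysis and tests run at desk scale, chosen as the package's
own study conditions: cohorts of 20,000 subjects with 100 covariates and
69 negative-control outcomes; plasmode replicates of 5,000 (20 per cell in
the analysis scripts; 100 in the truth-injection checks); the acceptance
experiments use 20 master seeds or replicates where a distribution over
runs is needed. Monte-Carlo tolerances follow from these sizes (binomial
bands for coverage, 2 MC SEs for recovery checks). Intercept calibration
bisects to $10^{-10}$; logistic fits for the 2×2-equivalent estimator use a
$10^{-12}$ IRLS tolerance so the closed-form equality holds to $10^{-6}$;
score vectors are clamped to $[0,1]$ against floating-point excursions of
the MLP output layer.

## Known limitations

* Synthetic covariates are exchangeable and purely binary; whether
  categorical structure (e.g., treatment year) changes the method ranking
  is not addressed.
* The time-varying exposure of the motivating design is emulated by the
  pseudo-index matched-cohort construction; the original index-date
  mechanics for comparators are not published and are not asserted here.
* The MLP is a single-hidden-layer network; deeper architectures and
  batch-level tuning are outside the R stack used here.
* No empirical CI calibration from negative controls, no SMOTE-style
  oversampling, no Super Learner ensembling, no out-of-sample DRS
  generalisation — all explicitly out of scope.
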