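---
title: "Latent class diagnostic accuracy for circulating endometrial cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class diagnostic accuracy for circulating endometrial cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecdx)
```

## The problem

Endometriosis has no perfect diagnostic reference standard. Laparoscopy,
the conventional "gold standard", misses subtle, subperitoneal, and
extra-pelvic lesions, so evaluating a new biomarker — here the circulating
endometrial cell (CEC) count in peripheral blood, alongside serum CA125 —
against laparoscopy as if it were truth would bias both the biomarker's
and laparoscopy's apparent accuracy. `cecdx` implements the alternative:
treat true disease status as a latent variable and estimate the operating
characteristics of all three tests jointly from their agreement pattern.

## The model

Each patient $i$ carries an unobserved disease status
$D_i \sim \mathrm{Bernoulli}(\pi)$. Given $D_i$, the $K$ binary tests
$Y_{i1}, \dots, Y_{iK}$ are conditionally independent with

$$P(Y_{ik} = 1 \mid D_i = 1) = Se_k, \qquad
  P(Y_{ik} = 0 \mid D_i = 0) = Sp_k,$$

the classical two-class Hui–Walter structure. The observed-data
log-likelihood is the two-component mixture

$$\ell = \sum_i \log\Big[\pi \prod_k Se_k^{y_{ik}}(1-Se_k)^{1-y_{ik}}
 + (1-\pi) \prod_k (1-Sp_k)^{y_{ik}} Sp_k^{1-y_{ik}}\Big],$$

with missing results skipped pairwise inside the products, so patients
diagnosed clinically without surgery still contribute through their
remaining tests. With three tests observed in a single population the
parameters are identifiable (up to the class-label swap) whenever every
test is informative.

Conditional independence given the latent class is an assumption, not a
theorem: it fails when two tests share an error mechanism. Laparoscopy,
CEC enumeration, and serum CA125 probe disease through very different
channels (surgical visualisation, shed cells in blood, a serum antigen),
which is the usual justification for adopting it here.

### Constraints and label anchoring

Two structural choices mirror the clinical situation:

* **Laparoscopy specificity is fixed at 1** (`study_constraints()`). A
  surgically visualised and histologically confirmed lesion is not a
  false positive; laparoscopy's weakness is missed disease. The fixed
  parameter is overwritten after every M-step, so it is never estimated.
  Its sensitivity remains free — that is precisely the quantity an
  imperfect-reference analysis must estimate.
* **Labels are anchored on laparoscopy**: after fitting, classes are
  relabelled if needed so that its Youden index $Se + Sp - 1$ is
  non-negative. Surgery may be insensitive but cannot plausibly be
  anti-informative. With the specificity constraint active the anchor is
  automatically satisfied; it matters for unconstrained fits.

### EM algorithm

`fit_lca()` maximises the likelihood by
expectation–maximisation. The E-step computes responsibilities
$\gamma_i = P(D_i = 1 \mid y_i)$ by Bayes' rule; the M-step updates
$\pi = \bar\gamma$ and each $Se_k$, $Sp_k$ as responsibility-weighted
positivity/negativity rates over the observed results. Numerical choices:

* patterns are collapsed before iterating (at most $3^K$ distinct rows),
  so cost is independent of cohort size;
* iterations are accelerated by squared polynomial extrapolation
  (SQUAREM-type scheme): plain EM crawls along the flat likelihood ridge
  created by the weakly informative CA125 arm, and the extrapolated
  update cuts the iteration count by an order of magnitude. A safeguard
  rejects any extrapolation that does not improve the log-likelihood and
  falls back to the plain double EM step, so the stored trace remains
  non-decreasing exactly as for unaccelerated EM;
* convergence at relative log-likelihood change below `tol = 1e-8`,
  capped at `max_iter = 5000`;
* 20 starts by default: one informed by naive cross-tabulation against
  the anchor test, the rest uniform random, best likelihood kept. The
  seed is mandatory — there is no wall-clock randomness anywhere in the
  package;
* parameters may reach the boundary of $[0,1]$; no penalty is applied
  (structurally constrained specificities print exactly 1.000);
* a start that empties a class is discarded and redrawn;
* zero-probability patterns (possible under hard constraints) resolve
  their posterior to the prior and are reported, not hidden.

The log-likelihood trace of the winning run is stored and is
non-decreasing by construction; the test suite asserts this on randomly
generated fixtures and also checks the achieved likelihood against a
brute-force lattice search on small cohorts.

### Covariate-varying accuracy

Prevalence and accuracies plausibly vary with pain severity. `fit_curve()`
estimates them as smooth functions of the VAS pain score by
kernel-weighted local likelihood: at a target score $v_0$ every patient's
log-likelihood contribution is weighted by $K((v_i - v_0)/h)$ and the same
constrained EM is run with those weights (a local-constant, Nadaraya–
Watson-type estimator — the simplest one consistent with a nonparametric
accuracy curve; a local-linear variant is out of scope). Kernels are
scaled so $K(0)=1$, making the weight sum an effective sample size; grid
points whose effective sample size falls below 10 are flagged rather than
silently extrapolated. Menstrual-cycle phase is handled by hard
stratification into the two pooled strata (proliferative + menstrual vs
secretory) rather than as a second smoothed covariate, matching the
two-panel presentation of phase-specific curves and avoiding a 2-d
smoother on a small cohort.

The default bandwidth is Silverman's reference rule
$1.06\,\mathrm{sd}(v)\,n^{-1/5}$; leave-one-out cross-validated selection
over a log-spaced candidate set is available (`select_bandwidth(method =
"cv")`) at $O(n\,|H|)$ refits. The infinite-bandwidth limit equals the
homogeneous fit, which the tests use as an anchor, and the default grid
is VAS 0–10 in steps of 0.25.

### Pooled estimates and intervals

For overall and phase-only analyses, point estimates come from an
imputation scheme (`impute_accuracy()`): draw
$D_i^{(m)} \sim \mathrm{Bernoulli}(\gamma_i)$ for $m = 1..M$ (default
$M = 50$), cross-tabulate each test against each imputed status vector,
and average. As $M$ grows this converges to the EM estimates; it is kept
because it extends unchanged to posteriors from the covariate model
(each patient evaluated at their own VAS via `posterior_from_curve()`)
and makes the "what was imputed" question explicit. Whether one imputes
latent status for everyone or only missing surgical results is genuinely
open; the package defaults to latent-status imputation and exposes the
posterior source.

All confidence intervals are percentile bootstrap over patients
(`bootstrap_ci()`, default $B = 1000$, 2.5/97.5 percentiles), refitting
the model and re-imputing within every replicate. Rubin-style
imputation-variance combination is deliberately not used — the bootstrap
already propagates both model and imputation uncertainty. Percentile
rather than BCa intervals: the simplest method consistent with
bootstrap-for-all-CIs; BCa is a possible extension. Replicates on which
the estimator fails are dropped and counted; more than 10% failures is an
error rather than a silent narrowing.

## The synthetic cohort generator

No patient-level data are distributable, so `simulate_cohort()` generates
cohorts with exactly the structure the analysis assumes: phase and VAS
from their marginals, latent status from the prevalence at (VAS, phase),
tests conditionally independent given status, and a hurdle model for the
CEC count — the binary detection layer is authoritative (guaranteeing the
configured Se/Sp exactly) and positive counts are zero-truncated Poisson
with mean 3.0 for true positives and 1.5 for false positives, near the
reported group means. Treatment multiplies the odds of CEC detection by
0.13; detected cells split small/large by a group-specific binomial
(74.06% small in untreated disease, 4.95% in controls, 12.5% under
treatment). `scenario_preset()` returns configurations whose generating
operating characteristics equal the published point estimates per stratum,
with stratum prevalences from the printed counts where derivable and the
overall 0.48 otherwise.

Defaults the study does not pin down, chosen once as clinically plausible
and documented as assumptions: the VAS marginal (point mass 0.38 at zero,
discretised Beta(1.2, 1.8) on 1–10; a continuous variant exists for curve
tests), phase frequencies (7/40/53%), the CA125 value distribution around
the 35 U/mL cut-off (values generated consistent with the positivity call
and rounded to two decimals so CSV round-trips are exact), the
worsening-flag rates (0.25 diseased / 0.05 healthy), and the malignant
fraction among controls (0.096).

What passing recovery tests on these cohorts shows is that the estimator
inverts the model it assumes at realistic sample sizes — not that real
CEC data satisfy conditional independence, nor that real accuracies are
constant within strata. The generator contains no conditional dependence
between tests, no measurement drift, and no informative missingness;
those failure modes are outside what the simulations can certify.

## Deterministic clinical rules

The classification layer is fixed by the study design: CEC positivity at
$\ge 1$ cell per 6 mL; CA125 positivity at $\ge 35$ U/mL (the
conventional cut-off; configurable); dysmenorrhea strata none/mild/
moderate/severe at VAS 0 / 1–3 / 4–6 / 7–10, with fractional scores
rounded half-up before lookup since the bands are defined on the integer
scale; active disease as marked six-month worsening plus VAS $\ge 6$
(a stratum-based "moderate-to-severe" reading is exposed as an option
because the two phrasings differ; the explicit cut is the default); and
menstrual pooled with proliferative. Detection summaries report the rate
and the mean count over all patients in the group, zeros included.

## Problem sizes used by the checks

The recovery simulations use 20 cohorts of n = 2000 per scenario and
compare seed-averaged estimates to the generating values within ±0.05.
The bootstrap-coverage property uses n = 500 with 200 outer replicates at
B = 200 (reported analyses default to B = 1000). The lattice oracle runs
on cohorts of n ≤ 60 with a 0.05-step grid. These sizes make the full
suite reproducible on a single CPU while keeping Monte-Carlo error well
inside the asserted tolerances.

## Known limitations

* Two latent classes only; no disease-severity spectrum.
* No conditional-dependence (random-effects) extension; if tests share
  error mechanisms, accuracies will be over- or under-stated.
* The CA125 arm is weakly informative (Youden index ≈ 0.12 overall),
  which leaves a flat likelihood ridge: single-cohort estimates of the
  reference test's sensitivity are variable even at n = 2000, and only
  seed-averaged recovery is tight. The wide per-fit spread is a property
  of the design, not of the optimiser.
* Asymptotic (information-based) standard errors are not provided;
  intervals are bootstrap-only.
* Stratified fits below n = 15 are flagged, not estimated.

## A worked example

```{r example, eval = FALSE}
library(cecdx)

cohort <- simulate_cohort(scenario_preset("overall", n = 500), seed = 1)
panel <- as_test_panel(cohort)
fit <- fit_lca(panel, seed = 1)
tidy(fit)

report <- accuracy_report(cohort, NULL, M = 50, B = 200, seed = 1)
format_accuracy(report)

curve <- fit_curve(cohort, stratum = "secretory", bandwidth = 1.5,
                   B = 0, seed = 1)
autoplot(curve)
```
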