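---
title: "ctDNA-adjusted bTMB: model, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctDNA-adjusted bTMB: model, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctbTMB)
```

## The problem and the score

Plasma-based tumor mutational burden (bTMB) counts the somatic mutations a
targeted cfDNA assay detects, per megabase of panel. Detection in plasma is
not a property of the tumor genome alone: it depends on how much
tumor-derived DNA circulates, and shedding scales with tumor size. Large
tumors therefore look hypermutated in plasma regardless of their actual
mutation load, and since bulky disease also carries a poor prognosis, raw
bTMB mixes a favorable signal (immunogenic mutation load) with an
unfavorable one (tumor burden). This is a candidate explanation for the
recurring observation that bTMB tracks response and PFS under checkpoint
inhibition but fails for overall survival.

The ctDNA input mass cannot be measured directly — cfDNA is mostly
leukocyte-derived — but it can be estimated as

$$\text{ctDNA mass} = \text{cfDNA input mass (ng)} \times \overline{\text{AF}},$$

the cfDNA mass times the mean allele fraction of somatic mutations. The
adjusted score divides the burden-sensitive count by this burden proxy:

$$\text{ctDNA-adjusted bTMB} = \frac{\text{bTMB}}{\text{cfDNA mass}\times\overline{\text{AF}}}
\quad [\text{muts}/(\text{Mb}\cdot\text{ng})].$$

In a sub-saturation detection regime (detection probability roughly
proportional to mean AF), the expected detected count is proportional to
(mutation load × mean AF), so the ratio cancels the shedding term and the
expected adjusted score is proportional to mutation load over cfDNA mass —
independent of tumor size. Report labels print the field's customary unit
"muts/Mb × ng"; dimensionally the formula divides by nanograms.

## Scoring conventions

Counting rules for plasma TMB are assay-specific and rarely published in
full; `eligibility_policy()` makes every deferral explicit:

| knob | default | meaning |
|---|---|---|
| `af_floor` | 0.005 | minimum AF for a call to count toward bTMB |
| `include_indels` | TRUE | indels count toward bTMB |
| `exclude_germline` | TRUE | germline-flagged calls removed everywhere |
| `exclude_drivers_from_btmb` | FALSE | drivers stay in the count |
| `mean_af_variant_set` | all_somatic | mean AF over all somatic calls, not the bTMB-eligible subset |
| `zero_mass_policy` | exclude | zero estimated ctDNA mass leaves the score undefined |
| `dcb_indeterminate` | exclude | censored before 6 months drops out of DCB labelling |

The mean AF uses *all* somatic calls because the ctDNA mass estimate
reflects total shedding; restricting it to bTMB-eligible calls is available
as a sensitivity analysis. A patient with no somatic calls has mean AF 0
and an undefined adjusted score; such patients are excluded from
score-based analyses by default (an epsilon-floor alternative exists for
sensitivity checks). Durable clinical benefit (DCB) is PFS ≥ 6 months,
boundary inclusive whether the 6-month mark is reached with an event or
under censoring; progression or death before 6 months is NDB.

## Cutoff selection and AUC comparison

The ROC orientation is "high score predicts DCB" with the rule
score ≥ threshold, one operating point per attained score value. The
trapezoidal AUC is exactly the tie-corrected Mann–Whitney concordance
(ties counted ½), an identity the test suite asserts to 1e-12. The optimal
cutoff maximizes Youden's J = sensitivity + specificity − 1; ties in J are
broken toward the smallest attaining score, i.e. the higher-sensitivity
operating point. Correlated AUCs (adjusted vs raw score on the same
patients) are compared with the paired DeLong test implemented from
placement values; `pROC` serves as an independent cross-check in the
tests, never as the implementation. By default the cutoff is derived on
ICI-arm patients only — the cutoff's job is to predict benefit *from
ICIs* — with an all-patients option; deriving and evaluating the cutoff on
the same cohort mirrors common practice, and the report flags the
optimism (a split-sample option exists).

## Survival machinery

Kaplan-Meier estimation, log-rank tests and Cox fitting stand on the
`survival` package (Efron ties by default, Breslow for cross-checking
against tools that default to it). Medians use the step-function
convention: the earliest time with S(t) ≤ 0.5, undefined if never reached.
Confidence intervals are 95% Wald throughout. The predictive-biomarker
question is the Wald test of the product term in
`~ treatment + marker + treatment:marker`; within-stratum treatment hazard
ratios are refit per stratum for forest-style reporting. Interaction
p-values carry no multiplicity adjustment, matching the two-tailed
p < 0.05 convention of the analyses this package systematizes. Monotone
partial likelihoods (perfect separation) and rank-deficient designs raise
diagnostic errors instead of silently returning extreme estimates.

The restricted cubic spline uses the classical truncated-power basis with
linear tails, normalized by the squared knot range, 4 knots at the
5/35/65/95th percentiles by default and the hazard-ratio reference at the
median score (HR(reference) = 1 exactly, by construction). The
nonlinearity test is the joint Wald test that the k − 2 nonlinear
coefficients vanish. `splines::ns` spans the same function space and is
used as an independent fitted-curve oracle in the tests.

## What the simulator emulates

`simulate_cohort()` generates the structure the analysis assumes, per
patient *i*:

- burden $B_i \sim \mathrm{LN}(4.0, 0.5)$ mm (sum of longest diameters);
- true panel mutation count $M_i \sim \mathrm{NB}(\mu = 10, k = 5)$;
- cfDNA input mass $C_i \sim \mathrm{LN}(3.2, 0.4)$ ng;
- mean shed AF $a_i = \min(0.30,\ 2\times10^{-4}\, B_i\,\varepsilon_i)$,
  $\varepsilon_i \sim \mathrm{LN}(0, 0.25)$ — shedding linear in tumor
  size;
- each mutation detected independently with probability
  $\min(1,\ 30\, a_i)$; detected variants receive AFs drawn mean-matched
  lognormally around $a_i$ (log-sd 0.45), conditioned on exceeding the
  assay limit of detection (0.005) — a caller reports no sub-LOD variants;
- OS and PFS exponential with log-hazard
  $\beta_T T + \beta_X \tilde X + \beta_{TX} T \tilde X + \beta_B z(\log B)$,
  baseline medians 12 and 4 months, $\beta_T = \log 0.85$,
  $\beta_{TX}^{OS} = \log 0.5$, $\beta_{TX}^{PFS} = \log 0.45$,
  $\beta_B = \log 1.3$ per SD of log-burden; administrative censoring
  uniform on 12–36 months;
- best response logistic in $T\tilde X$ (intercept −1.5, slope 1.2), with
  responders' progression times floored at 2 months so response and PFS
  cannot contradict each other.

Two design choices deserve emphasis.

**The latent group is defined on the expected score.** The
biomarker-high indicator $\tilde X_i$ that drives survival is
$\mathbb{E}[\text{adjusted score} \mid M_i, C_i, a_i] =
M_i \min(1, 30 a_i)/(P\, C_i\, a_i) \ge 8$, not the realized noisy score.
This keeps $\tilde X$ genuinely latent (the observed score is its noisy
measurement, as in real data), makes its prevalence computable by
numerical integration of the generative distributions — an oracle the test
suite uses — and is the quantity the parameter-recovery checks (Cox on
$(T, \tilde X, T\tilde X)$) presuppose. With detected counts averaging
~3.6, the realized score misclassifies roughly a fifth of patients against
$\tilde X$, which attenuates interaction estimates based on the observed
grouping — visible in the pipeline output as stratified hazard ratios
closer together than the generating coefficients.

**Reported AFs are LOD-truncated.** Variant callers do not emit calls
below their limit of detection, so per-variant AFs are drawn from the
lognormal conditioned on exceeding 0.005 (the default eligibility floor).
This is not cosmetic: with untruncated draws, the AF floor deletes counts
specifically from low-burden patients (whose mean AF sits near the floor),
re-coupling the adjusted score to burden from one side, while conditioning
on ≥ 1 detected variant couples it from the other. Under the truncated
construction with AF spread 0.45 the two small-count effects cancel and
the generator exhibits the burden-independence the adjusted score is
defined to have (|Spearman ρ| < 0.05 at n = 2000), alongside a raw-bTMB
correlation of ρ ≈ 0.5.

Randomness is keyed per patient: every patient draws from a substream
derived from (seed, index), clinical draws and variant-annotation draws in
separate substreams. Extending the cohort never reshuffles earlier
patients, and the variant table can be skipped for survival-only
simulation studies without changing a single clinical outcome.

**What the generator does not emulate.** No read-level sequencing error,
no clonal-hematopoiesis contamination (germline-flagged calls appear at a
token rate only to exercise the somatic filter), no dependence between OS
and PFS beyond shared covariates (so PFS can exceed OS — the readers
accept and warn on such records, as registry data require), no panel-
or site-specific effects. Passing tests therefore demonstrate that the
pipeline's statistics behave correctly under the stated generative model,
not that the adjustment conquers every bias in real plasma assays —
clonal hematopoiesis in particular remains an open concern and enters
only as a configuration hook (the germline-exclusion policy).

## Numerical and degenerate-input conventions

- Cox convergence is delegated to `survival::coxph`; fits with runaway
  coefficients (|β| > 15 or a flagged infinite coefficient) raise a
  divergence error.
- The log-rank χ² equals the squared Cox score statistic (Breslow) only
  for untied event times; the identity test uses continuous times.
- Exact small-sample paths: Mann–Whitney p is enumerated when
  n·m ≤ 400 without ties; Spearman p is exact for n ≤ 9 without ties;
  Fisher's two-sided p uses the point-probability rule (doubling rule
  available).
- Chi-square defaults to no continuity correction; the pipeline picks
  Fisher when any expected cell is below 5.
- Empty cohorts, single-class labels, zero-variance vectors, zero
  marginals, degenerate knot quantiles and empty interaction cells all
  raise typed errors naming the offence rather than propagating NaNs.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to bound Monte-Carlo error while
staying light: the decorrelation property at n = 2000; interaction-test
size at 2000 replicates of n = 300 (rejection rate expected in
[0.03, 0.07] at α = 0.05); interaction recovery at 500 replicates of
n = 600 (mean within ±0.1 of log 0.5, CI coverage in [0.92, 0.98]); spline
nonlinearity calibration at 1000 replicates of n = 300 under a linear
log-hazard; exactness oracles at 500–1000 random instances each. The
acceptance script (`scripts/acceptance.R`) reruns the full pipeline at
n = 2000 and a 400-replicate null calibration, writing every quantity it
computes as JSON.

## Known limitations

The adjusted score is undefined for patients with no detected somatic
variants — about 10% under the default generator — and excluding them
conditions analyses on detectability. The derived cutoff is optimistic
when evaluated on the cohort that produced it. The simulator's exponential
hazards satisfy proportional hazards by construction; the package's only
PH diagnostic is the spline linearity probe on the score. Serial
(on-treatment) measurements and tissue-TMB concordance are out of scope.
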