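---
title: "Methods: joint gene-lifestyle analysis of incident hypertension"
author: "genelife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint gene-lifestyle analysis of incident hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genelife)
```

This vignette is the package's own account of the statistical procedure
it implements, the choices that were genuinely open and how they were
resolved, what the synthetic-cohort generator does and does not emulate,
and the numerical conventions used throughout.

## The analysis

The pipeline targets a 3-year incident-hypertension cohort design:
subjects free of hypertension at baseline, re-measured once at
follow-up. A subject is an incident case when follow-up SBP ≥ 140 mmHg,
or follow-up DBP ≥ 90 mmHg, or they report antihypertensive medication
use within two weeks of the follow-up visit (`derive_outcome()`). Both
boundaries are inclusive. Cohort tables are validated against this
definition on entry, so a table that passes `validate_cohort()` is
internally consistent by construction.

### Lifestyle score

Five binary factors, each 1 when healthful:

| factor   | healthful when                          | default rule source |
|----------|-----------------------------------------|---------------------|
| diet     | CHEI ≥ 17                               | fixed threshold; empirical top-40% mode available |
| BMI      | 18.5 ≤ BMI < 24 kg/m²                   | sensitivity option: upper cutoff 25 |
| smoking  | never, or quit ≥ 30 years ago           | boundary inclusive |
| activity | IPAQ moderate or high                   | |
| drinking | ≤ 12 drinking occasions in the past year | "more than 12" is strict |

The CHEI diet sub-score maps each of nine food-frequency items to 0–4
points (daily = 4 … never = 0 for the eight beneficial foods; red meat
reverse-scored), giving a theoretical range of 0–36. Published cohort
summaries sometimes report narrower observed ranges (e.g. 3–28); we
treat such figures as realized sample ranges, not constraints on the
score's support — the stated per-item mapping forces 0–36.

Two boundary conventions deserve a note. First, the BMI band: verbal
definitions of the form "18.5 to 23.9 healthful, under 18.5 and over 24
unhealthful" leave (23.9, 24.0) undefined; we close the band as
[18.5, 24), which reproduces both stated endpoints and leaves no gap.
Second, the diet cutoff defaults to the *fixed* printed threshold
(≥ 17) rather than the cohort's empirical 60th percentile, so results
are reproducible on any cohort without access to the original data; the
empirical mode (`chei_cutoff_mode = "empirical_top40pct"`) restores the
self-referential definition.

The score (0–5) is the count of healthful factors; groups are 0–1
unhealthful, 2–3 intermediate, 4–5 healthful.

### Genetic risk score

Each of the 13 SNPs is genotyped into three classes; the non-risk
homozygote is the reference (this makes "all-reference → GRS = 0" well
defined). Effect values are estimated *in the study sample*: one
regression per SNP of the outcome on the two genotype dummies, with no
covariates. The per-dummy coefficients are the effect values, and a
subject's GRS is their sum across loci. The outcome of these
regressions is configurable (`grs_effect_outcome`): logistic on
incident hypertension (default) or linear on follow-up SBP. Whether the
original effect values came from adjusted or unadjusted models, and
against which outcome, is not derivable from the published text; both
options are exposed and neither is asserted as "the" published choice.
A user-supplied weight table (external GWAS betas) can be passed to
`score_cohort()` in place of in-sample estimation.

Degenerate loci — monomorphic, an empty genotype cell, or separation —
contribute effect values of 0 with a warning rather than failing the
whole pipeline; subjects with any missing genotype get `NA` GRS and are
excluded from GRS-dependent analyses (with a logged count), but remain
in lifestyle-only analyses.

Risk groups are empirical tertiles (type-7 quantiles). Ties at a
cutpoint are broken by stable subject order (first-come, lower group),
which keeps group sizes within 2 of each other under any tie pattern;
for untied data the partition coincides with value-based tertile
cutpoints. If every GRS is identical the partition is undefined and all
subjects are assigned to the low group with a warning.

### Association models

Logistic regression (maximum likelihood, IRLS to a relative
log-likelihood tolerance of 1e-10, at most 100 iterations) for
hypertension; Gaussian identity-link least squares for follow-up SBP
and DBP, with baseline SBP and DBP among the covariates rather than
modeling change scores. All intervals are Wald 95% CIs. Rank-deficient
designs are rejected with the collinear columns named; apparent
separation (non-convergence or |coefficient| > 15) is a flagged error
naming the column.

The three model tags follow the conventional escalation: model 1 crude;
model 2 adjusted for age, sex, family history of hypertension,
education, marriage, income, baseline SBP and baseline DBP; model 3
additionally mutually adjusted (lifestyle and GRS in the same model).
Categorical covariates enter as dummies (income and education are not
assumed ordinal).

One covariate deviation is deliberate: the antihypertensive-medication
flag is *excluded* from models of the hypertension outcome, though it
stays in the covariate set for SBP/DBP. Medication use is a component
of the outcome definition — every medicated subject is a case — so in
any internally consistent cohort the flag perfectly predicts case
status and produces tautological quasi-complete separation. Adjusting
for part of the outcome is not estimable, and no finite coefficient
exists for it.

The joint analysis fits, per outcome, a single model with eight dummies
for the non-reference cells of the 3×3 GRS-group × lifestyle-group grid
(reference: low GRS, healthful lifestyle) plus the covariates — one
9-cell model with a common reference rather than per-stratum models,
matching the single-reference design of the grid. Empty cells are
flagged sparse and omitted from the design rather than aborting.

### Additive interaction (RERI)

Exposures are dichotomized as: lifestyle risk = intermediate or
unhealthful group (i.e. score ≤ 3); genetic risk = GRS at or above the
cohort median, the tie at the median going to the upper half ("upper
50th percentile" read inclusively). For the binary outcome,

RERI = OR₁₁ − OR₁₀ − OR₀₁ + 1,  OR₁₁ = exp(βA + βB + βAB),

estimated from a logistic model with both exposures and their product.
The default CI is the delta method with gradient
(OR₁₁ − OR₁₀, OR₁₁ − OR₀₁, OR₁₁) applied to the covariance block of
(βA, βB, βAB); a seeded subject-resampling bootstrap is the optional
check. Odds ratios approximate risk ratios here; with ~19% incidence
the approximation is imperfect, which is a caveat on interpretation,
not on the arithmetic. For the continuous outcomes the additive
contrast of adjusted means, β₁₁ − β₁₀ − β₀₁, collapses algebraically to
the product-term coefficient, so the "continuous RERI" is that
coefficient with its Wald interval — a stated interpretation, since no
canonical continuous-outcome RERI exists.

Note one property that surprises at first sight: under purely
multiplicative joint effects (no product term on the log-odds scale)
the additive-scale RERI is generally *positive*, not zero. The
generator's default, product-term-free configuration therefore has an
analytic RERI of about 0.22, and the test suite checks interval
coverage against that value, not against zero.

### Epidemiological indicators

With incidences Iₑ (exposed, score 0–3), Iᵤ (unexposed, score 4–5) and
Iₜ (whole population):

* RR = Iₑ/Iᵤ, AR = (Iₑ − Iᵤ)·100, PAR = Iₜ − Iᵤ,
  PAR% = (Iₜ − Iᵤ)/Iₜ·100;
* PFP = (Iₑ − Iₜ)/Iₑ·100 and morbidities averted = N·(Iₑ − Iₜ), where
  the healthful lifestyle is the protective exposure and the
  no-exposure counterfactual incidence is Iₑ (everyone exposed to the
  unfavorable lifestyle).

PAR is reported on the proportion scale with PAR% alongside: published
panels of this design print proportion-scale PAR values (0.04) under a
"%" label, and exposing both scales reproduces that convention while
keeping the units honest. All values are carried at full precision;
display rounding is 2 decimals, half-up, applied only at print time. No
CIs are attached to the indicators by default (crude indicators, as is
conventional for this panel); the algebraic identities
PAR% = PAR/Iₜ·100, AR = (RR − 1)·Iᵤ·100 and
averted = events·PFP/(100 − PFP) hold to numerical precision and are
enforced in the test suite. The per-GRS-stratum table uses each
stratum's own population margin, so the sum of per-stratum averted
counts need not equal the pooled value; both are printed side by side.

## The synthetic-cohort generator

No individual-level data accompany the published analysis, so the
generator (`sim_config()`, `generate_cohort()`) emulates the cohort's
published marginal structure and lets every downstream stage be tested
against known truth. Its defaults *are* the study conditions:

* unhealthful-state prevalences diet 60.37%, BMI 51.70%, smoking
  26.44%, activity 49.00%, drinking 12.80%;
* baseline SBP 116.06 ± 11.44 and DBP 73.62 ± 7.59 mmHg, drawn
  truncated below the 140/90 cutoffs (the cohort is hypertension-free
  at baseline) with the location shifted so the truncated mean matches
  the printed mean;
* covariate margins: age 49.04 ± 11.52, 36.93% men, education
  46.0/42.7/11.3%, 92.85% married, income 91.1/6.7/2.2%, 30.36% family
  history;
* an overall 3-year incidence of 18.9%, via a reference-category
  incidence of 0.0518 calibrated once against the expectation of the
  outcome model under the default effect sizes;
* per-genotype odds ratios of 1.139 (het) and 1.297 (hom) at all 13
  loci — per-SNP frequencies and effects were never published, so these
  are illustrative values chosen (with allele frequencies 0.20–0.45) so
  that the *emergent* high-vs-low GRS tertile odds ratio is near 1.9,
  the magnitude reported for this design; the implied GRS linear
  predictor has SD ≈ 0.30;
* per-factor odds ratios 1.15 (diet), 1.40 (BMI), 1.10 (smoking), 1.10
  (activity), 1.15 (drinking).

Genotypes are drawn per SNP under Hardy–Weinberg at the configured
allele frequency, independently across loci (no linkage
disequilibrium). Binary lifestyle states are drawn at the configured
prevalences, then *raw* variables are constructed to be exactly
consistent with them: a CHEI target is drawn on the intended side of
the 17-point cutoff and decomposed into nine item scores summing
exactly to it (binomial initialization plus a residual-adjustment
sweep, so item distributions look natural); BMI comes from a mixture
straddling the healthy band (8% of unhealthful subjects below 18.5);
smoking status and quit-years, IPAQ level and drinks/year are drawn
within the correct class. The scoring classifiers therefore invert the
generator exactly, which is what makes the realized prevalences land on
their targets.

Incident hypertension is drawn from a logistic model whose linear
predictor sums the configured per-genotype and per-factor log-ORs. By
default there is no gene-lifestyle product term
(`interaction_reri_target = 0`); a nonzero target calibrates a
product-term coefficient by root-finding on the additive-scale RERI of
the collapsed 2×2 cell risks, computed from the noise-free expectation
of the draw itself (a calibration error is raised if the target is
unreachable).

Follow-up pressures are linear in baseline pressure with per-exposure
mmHg shifts, a +10/+5 mmHg case shift and Gaussian residuals (SD 8/6).
The outcome draw and the pressures are then reconciled so the
cohort-table invariant holds: a case whose drawn pressures sit below
the cutoffs gets the medication flag (a treated, controlled patient); a
non-case whose pressures reached a cutoff has them redrawn below it.
One consequence worth knowing: most synthetic cases are
"medication-detected", which mirrors the selection problem real cohorts
report when treated patients' measured pressures are controlled.

Covariates are drawn independently of both exposures and outcome. This
is deliberate: it makes analytic expectations of the estimators
checkable (crude and adjusted estimates coincide in expectation up to
non-collapsibility), at the price of realism — the generator does not
emulate confounding, age-BP gradients, questionnaire measurement error,
or longitudinal BP trajectories. Passing tests therefore demonstrate
that the estimators recover known structure, not that the generator
reproduces every joint distribution of a real cohort.

All randomness flows from the single seed in `sim_config()`; the
generator saves and restores the caller's RNG state, and identical
configurations produce identical tables.

## Numerical conventions and degenerate inputs

* Quantiles are type-7 (linear interpolation) everywhere.
* GLM convergence: epsilon 1e-10, max 100 iterations; |coefficient| >
  15 on a dummy is treated as separation.
* Display rounding: 2 decimals, half-up, print-time only.
* Degenerate inputs have documented behaviors rather than crashes:
  empty exposure or unexposed groups block the indicator panel with a
  named error; all-identical GRS puts everyone in the low group with a
  warning; monomorphic SNPs contribute zero effect values with a
  warning; empty grid cells are flagged sparse.

## Problem sizes used in the test suite

The suite exercises the estimators at the sizes the properties need:
single cohorts of n = 20,000 for effect recovery and marginal checks, a
seeded n = 150,000 reference draw for the emergent group-level
contrasts, 200 replicates of n = 4,000 for CI coverage of the
configured factor effects, and 100 replicates of n = 20,000 for RERI
interval coverage against the analytic value from a noise-free
n = 200,000 expectation draw. These sizes were chosen so that
Monte-Carlo error is small relative to each tolerance being asserted.

## Known limitations

* In-sample effect values make the GRS mildly overfit by construction
  (the same data estimate the weights and the association); the paper's
  design shares this property. External weights avoid it.
* OR-based RERI at ~19% incidence overstates the risk-ratio analog.
* The generator's independence assumptions (no confounding, no LD, no
  measurement error) are simplifications, as discussed above.
* Crude indicators carry no sampling uncertainty by default; a seeded
  bootstrap exists in the RERI machinery but is not wired to the
  indicator panel.
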