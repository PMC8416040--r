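# genelife

Joint gene–lifestyle analysis of incident hypertension for cohort
studies: a five-factor healthy-lifestyle score, an in-sample genetic risk
score over 13 blood-pressure loci, separate and joint regression models,
additive interaction (RERI), and a panel of population-impact indicators.
A seeded synthetic-cohort generator makes the whole pipeline testable
without access to individual-level data.

## The science

**Lifestyle score.** Five factors are each dichotomized healthful (1) /
unhealthful (0) and summed to a 0–5 score:

* *Diet*: a 9-item food-frequency diet-quality score (CHEI). Eight
  beneficial foods score daily = 4 … never = 0; red meat is
  reverse-scored. Diet is healthful when CHEI ≥ 17 (or, optionally, in
  the cohort's own top 40%).
* *BMI*: healthful in [18.5, 24) kg/m² (sensitivity option: upper cutoff
  25, the WHO overweight threshold).
* *Smoking*: never smoked, or quit ≥ 30 years ago.
* *Physical activity*: IPAQ moderate or high.
* *Drinking*: at most 12 drinking occasions in the past year.

Scores 0–1, 2–3 and 4–5 form the unhealthful, intermediate and healthful
lifestyle groups.

**Genetic risk score.** For each of 13 SNPs, the two non-reference
genotypes are dummy-coded against the non-risk homozygote and their
effect values estimated in the study sample itself (single-SNP logistic
regression on incident hypertension by default). A subject's GRS is the
sum of the effect values of their genotypes; tertiles define low /
intermediate / high genetic risk.

**Outcome.** Incident hypertension over the follow-up window: SBP ≥ 140
mmHg or DBP ≥ 90 mmHg at follow-up, or antihypertensive medication
within two weeks.

**Models.** Logistic regression for hypertension and Gaussian linear
models for follow-up SBP/DBP: exposure-group contrasts (model 1 crude,
model 2 covariate-adjusted, model 3 mutually adjusted) and a joint 3×3
GRS-by-lifestyle grid against the low-GRS/healthful-lifestyle reference
cell.

**Additive interaction.** RERI = OR₁₁ − OR₁₀ − OR₀₁ + 1 for the
dichotomized exposures (healthful vs. other lifestyle; GRS upper vs.
lower half), with a delta-method or bootstrap CI; for the continuous BP
outcomes the additive contrast equals the product-term coefficient.

**Population impact.** With incidences *Iₑ* (exposed, lifestyle score
0–3), *Iᵤ* (unexposed, score 4–5) and *Iₜ* (total):
RR = *Iₑ*/*Iᵤ*; AR = (*Iₑ* − *Iᵤ*)·100; PAR = *Iₜ* − *Iᵤ*;
PAR% = (*Iₜ* − *Iᵤ*)/*Iₜ*·100; PFP = (*Iₑ* − *Iₜ*)/*Iₑ*·100; morbidities
averted = *N*·(*Iₑ* − *Iₜ*). PFP treats the healthful lifestyle as the
protective exposure whose current prevalence is already averting cases.

## Worked example

```r
library(genelife)

cohort <- generate_cohort(sim_config(n_subjects = 4592, seed = 1))
res <- run_pipeline(cohort)
print(res$indicators)
#> Epidemiological indicators by genetic risk subgroup
#>                     overall     low intermediate    high
#> n                   4592.00 1531.00      1530.00 1531.00
#> events               815.00  196.00       247.00  372.00
#> incidence_pct         17.75   12.80        16.14   24.30
#> rr                     1.40    1.29         1.35    1.50
#> ar                     5.59    3.05         4.58    9.09
#> par                    0.04    0.02         0.03    0.06
#> par_pct               21.64   16.55        19.15   25.88
#> pfp                    8.98    6.79         8.46   10.34
#> morbidities_averted   80.40   14.28        22.83   42.92
#> Sum of per-stratum morbidities averted: 80.02 (pooled: 80.40)
```

Reading the overall column: subjects with an unfavorable lifestyle
(score 0–3) developed hypertension 1.40 times as often as those with a
favorable one; their excess incidence was 5.59 percentage points; 21.64%
of all incident cases are attributable to unfavorable lifestyle; and the
current prevalence of favorable lifestyles is already averting about 80
cases (9.0% of the counterfactual burden) in this cohort of 4,592.

Adjusted association models and the interaction panel:

```r
subset(res$associations,
       outcome == "hypertension" & model_tag == "model3" & exposure == "grs")
#>         outcome exposure model_tag        level estimate conf.low conf.high
#>    hypertension      grs    model3          low     1.00     1.00      1.00
#>    hypertension      grs    model3 intermediate     1.33     1.08      1.62
#>    hypertension      grs    model3         high     2.21     1.82      2.67

print(res$reri, digits = 3)
#>        outcome estimate ci_low ci_high method
#> 1 hypertension    0.633  0.204    1.06  delta
#> 2          sbp    0.309 -0.715    1.33  delta
#> 3          dbp    0.289 -0.457    1.04  delta
```

Reading a cohort from disk instead:

```r
path <- system.file("extdata", "example_cohort_synthetic.csv", package = "genelife")
cohort <- read_cohort(path)          # validates schema + invariants
scored <- score_cohort(cohort)       # CHEI, factors, lifestyle & GRS groups
```

A thin command-line wrapper lives at `inst/scripts/genelife.R`
(`simulate`, `score`, `indicators`, `run` subcommands).

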