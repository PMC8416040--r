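Package: genelife
Title: Joint Gene-Lifestyle Analysis of Incident Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cohort studies of incident hypertension that combine a
    five-factor healthy-lifestyle score (diet quality, body-mass index,
    smoking, physical activity, drinking) with an in-sample genetic risk
    score built from genotype dummy-variable effect values across 13 blood
    pressure loci. Provides cohort table validation and a seeded synthetic
    cohort generator; separate and joint logistic and linear association
    models with covariate adjustment; additive interaction via the relative
    excess risk due to interaction (RERI) with delta-method or bootstrap
    confidence intervals; and an epidemiological indicator panel (relative
    risk, attributable risk, population attributable risk and fraction,
    prevented fraction for the population, morbidities averted), overall
    and within genetic risk subgroups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
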