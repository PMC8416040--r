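#' Column vocabulary for cohort tables
#'
#' The cohort table is a plain delimited text file, one row per subject,
#' with a fixed header vocabulary. These helpers expose the vocabulary so
#' that generators, readers and tests agree on it.
#'
#' @name schema
NULL

#' SNP panel of the genetic risk score
#'
#' The 13 blood-pressure-associated loci genotyped in the cohort. Genotype
#' columns in a cohort table are named by these rsIDs and hold one of the
#' labels `"ref"` (homozygote of the non-risk allele), `"het"`
#' (heterozygote), `"hom"` (risk-allele homozygote), or `NA` for a failed
#' assay.
#'
#' @return Character vector of 13 rsIDs.
#' @export
gl_snps <- function() {
  c("rs11191548", "rs1275988", "rs16849225", "rs7136259", "rs17249754",
    "rs2107595", "rs9810888", "rs10745332", "rs1378942", "rs16998073",
    "rs1902859", "rs2021783", "rs7577262")
}

#' Food-frequency items of the diet-quality score
#'
#' Nine food groups scored by consumption frequency. All items except red
#' meat are beneficial (daily scores highest); red meat is reverse-scored.
#' Cohort columns are named `ff_<item>` and hold one of
#' `"daily"`, `"weekly"`, `"monthly"`, `"annually"`, `"never"`.
#'
#' @return Character vector of 9 item names, red meat last.
#' @export
gl_food_items <- function() {
  c("whole_grains", "fish", "eggs", "dairy", "vegetables", "fruits",
    "bean_products", "nuts", "red_meat")
}

gl_genotype_levels <- function() c("ref", "het", "hom")
gl_freq_levels     <- function() c("daily", "weekly", "monthly", "annually", "never")
gl_sex_levels       <- function() c("male", "female")
gl_education_levels <- function() c("primary_or_below", "junior", "senior_or_above")
gl_marital_levels   <- function() c("married_cohabit", "other")
gl_income_levels    <- function() c("lt1000", "1000to2999", "ge3000")
gl_ipaq_levels      <- function() c("low", "moderate", "high")
gl_smoking_levels   <- function() c("never", "former", "current")
gl_lifestyle_groups <- function() c("unhealthful", "intermediate", "healthful")
gl_grs_groups       <- function() c("low", "intermediate", "high")

#' @rdname schema
#' @return `gl_cohort_columns()` returns the required column names of a
#'   cohort table, in canonical order.
#' @export
gl_cohort_columns <- function() {
  c("subject_id", "age", "sex", "education", "marital", "income",
    "family_history_htn", "antihypertensive_med",
    "baseline_sbp", "baseline_dbp", "followup_sbp", "followup_dbp",
    "hypertension",
    paste0("ff_", gl_food_items()),
    "bmi", "smoking", "years_since_quit", "ipaq_level", "drinks_per_year",
    gl_snps())
}

# covariates usable in adjusted models, mapped to their column and coding
gl_covariate_vocabulary <- function() {
  c("age", "sex", "antihypertensive_med", "family_history_htn",
    "education", "marital", "income", "baseline_sbp", "baseline_dbp")
}
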