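#' Analysis configuration
#'
#' One declarative object holds every analysis choice that the study design
#' leaves open, with defaults matching the primary analysis: the 18.5-24
#' BMI band, the fixed diet-quality threshold of 17, genotype effect values
#' from single-SNP logistic models of incident hypertension, tertile
#' genetic risk groups, the full covariate set, and delta-method RERI
#' confidence intervals.
#'
#' @param bmi_rule `"primary"` (healthful BMI in \[18.5, 24)) or
#'   `"sensitivity25"` (upper cutoff 25 kg/m2, the WHO overweight
#'   threshold, used as a sensitivity analysis).
#' @param chei_cutoff_mode `"fixed_threshold"` classifies a diet healthful
#'   when CHEI >= `chei_fixed_threshold`; `"empirical_top40pct"` uses the
#'   cohort's own 60th percentile so that the top 40% of diets are
#'   healthful.
#' @param chei_fixed_threshold Integer threshold for the fixed mode.
#' @param grs_effect_outcome Outcome of the per-SNP effect-value
#'   regressions: `"hypertension_logistic"` or `"sbp_linear"` (follow-up
#'   SBP).
#' @param grs_group_mode `"tertile"` or `"custom_percentiles"`.
#' @param grs_percentiles Strictly increasing cutpoints in (0, 1); used
#'   only in `"custom_percentiles"` mode.
#' @param covariate_set Covariates for adjusted models; any subset of
#'   age, sex, antihypertensive_med, family_history_htn, education,
#'   marital, income, baseline_sbp, baseline_dbp.
#' @param reri_ci_method `"delta"` or `"bootstrap"`.
#' @param bootstrap_reps Bootstrap replicates when `reri_ci_method =
#'   "bootstrap"`.
#' @param seed Integer seed for any resampling.
#' @return An object of class `gl_config`.
#' @export
analysis_config <- function(bmi_rule = c("primary", "sensitivity25"),
                            chei_cutoff_mode = c("fixed_threshold", "empirical_top40pct"),
                            chei_fixed_threshold = 17L,
                            grs_effect_outcome = c("hypertension_logistic", "sbp_linear"),
                            grs_group_mode = c("tertile", "custom_percentiles"),
                            grs_percentiles = c(1 / 3, 2 / 3),
                            covariate_set = gl_covariate_vocabulary(),
                            reri_ci_method = c("delta", "bootstrap"),
                            bootstrap_reps = 500L,
                            seed = 1L) {
  cfg <- list(
    bmi_rule = match.arg(bmi_rule),
    chei_cutoff_mode = match.arg(chei_cutoff_mode),
    chei_fixed_threshold = as.integer(chei_fixed_threshold),
    grs_effect_outcome = match.arg(grs_effect_outcome),
    grs_group_mode = match.arg(grs_group_mode),
    grs_percentiles = as.numeric(grs_percentiles),
    covariate_set = covariate_set,
    reri_ci_method = match.arg(reri_ci_method),
    bootstrap_reps = as.integer(bootstrap_reps),
    seed = as.integer(seed))

  unknown <- setdiff(cfg$covariate_set, gl_covariate_vocabulary())
  if (length(unknown) > 0)
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (cfg$bootstrap_reps < 1) stop("bootstrap_reps must be >= 1", call. = FALSE)
  if (length(cfg$grs_percentiles) < 1 ||
      any(diff(c(0, cfg$grs_percentiles, 1)) <= 0))
    stop("grs_percentiles must be strictly increasing within (0, 1)",
         call. = FALSE)
  if (cfg$chei_fixed_threshold < 0 || cfg$chei_fixed_threshold > 36)
    stop("chei_fixed_threshold must lie in [0, 36]", call. = FALSE)
  structure(cfg, class = "gl_config")
}

#' @export
print.gl_config <- function(x, ...) {
  cat("<gl_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-21s %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
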