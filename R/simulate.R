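#' Simulation configuration for synthetic cohorts
#'
#' Defines the data-generating process of [generate_cohort()]. Defaults
#' emulate the study conditions of a rural Chinese hypertension cohort:
#' the five unhealthful-lifestyle prevalences, baseline blood pressure
#' moments and covariate margins match the cohort's published
#' characteristics table; per-SNP genotype odds ratios are illustrative
#' values calibrated so that the emergent high-vs-low GRS tertile odds
#' ratio is near 1.88; the reference-category incidence is calibrated so
#' that the overall 3-year incidence is near 18.9%. Per-SNP allele
#' frequencies and effect sizes were not published and are illustrative,
#' not reproductions.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; all randomness flows from it.
#' @param allele_freq Named numeric vector of 13 risk-allele frequencies
#'   in (0, 1), names from [gl_snps()].
#' @param genotype_or Data frame with columns `snp`, `het_or`, `hom_or`:
#'   per-genotype odds ratios for hypertension versus the non-risk
#'   homozygote.
#' @param lifestyle_prevalence Named probabilities of the *unhealthful*
#'   state for `diet`, `bmi`, `smoking`, `activity`, `drinking`.
#' @param lifestyle_or Named per-factor odds ratios of hypertension for
#'   the unhealthful versus healthful state.
#' @param interaction_reri_target Additive-interaction target on the RERI
#'   scale between the dichotomized lifestyle and genetic exposures. 0
#'   (the default) omits the product term entirely; note that purely
#'   multiplicative joint effects still imply a positive analytic RERI. A
#'   nonzero value calibrates a product-term coefficient by root-finding
#'   on a large expectation draw.
#' @param baseline_prevalence Incidence in the reference category (all
#'   genotypes `ref`, all five factors healthful).
#' @param bp_model Follow-up blood pressure model: for each of `sbp` and
#'   `dbp`, `intercept` (mmHg), `baseline_slope`, `per_unhealthful` (named
#'   mmHg shifts per unhealthful factor), `per_allele` (mmHg per risk
#'   allele) and `resid_sd`; plus `baseline` means/SDs for the two
#'   baseline pressures (drawn truncated below the 140/90 hypertension
#'   cutoffs, with the location shifted so the truncated mean matches).
#' @param covariate_distributions Age mean/SD, male proportion, category
#'   probabilities for education and income, married and family-history
#'   proportions.
#' @return Object of class `gl_sim_config`.
#' @export
sim_config <- function(n_subjects = 4592L,
                       seed = 1L,
                       allele_freq = NULL,
                       genotype_or = NULL,
                       lifestyle_prevalence = c(diet = 0.6037, bmi = 0.5170,
                                                smoking = 0.2644, activity = 0.4900,
                                                drinking = 0.1280),
                       lifestyle_or = c(diet = 1.15, bmi = 1.40, smoking = 1.10,
                                        activity = 1.10, drinking = 1.15),
                       interaction_reri_target = 0,
                       baseline_prevalence = 0.0518,
                       bp_model = NULL,
                       covariate_distributions = NULL) {
  snps <- gl_snps()
  if (is.null(allele_freq))
    allele_freq <- stats::setNames(
      c(0.30, 0.25, 0.40, 0.35, 0.38, 0.22, 0.45, 0.33, 0.28, 0.20, 0.36,
        0.31, 0.26), snps)
  if (is.null(genotype_or))
    genotype_or <- data.frame(snp = snps,
                              het_or = rep(exp(0.13), 13),
                              hom_or = rep(exp(0.26), 13),
                              stringsAsFactors = FALSE)
  if (is.null(bp_model))
    bp_model <- list(
      baseline = list(sbp_mean = 116.06, sbp_sd = 11.44,
                      dbp_mean = 73.62, dbp_sd = 7.59),
      sbp = list(intercept = 36, baseline_slope = 0.70, resid_sd = 8,
                 per_unhealthful = c(diet = 1, bmi = 2, smoking = 0.5,
                                     activity = 0.5, drinking = 0.5),
                 per_allele = 0.30, case_shift = 10),
      dbp = list(intercept = 21, baseline_slope = 0.70, resid_sd = 6,
                 per_unhealthful = c(diet = 0.5, bmi = 1.2, smoking = 0.3,
                                     activity = 0.3, drinking = 0.3),
                 per_allele = 0.15, case_shift = 5))
  if (is.null(covariate_distributions))
    covariate_distributions <- list(
      age_mean = 49.04, age_sd = 11.52,
      p_male = 0.3693,
      education_probs = c(primary_or_below = 0.4599, junior = 0.4273,
                          senior_or_above = 0.1128),
      p_married = 0.9285,
      income_probs = c(lt1000 = 0.9110, `1000to2999` = 0.0672, ge3000 = 0.0218),
      p_family_history = 0.3036)

  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              allele_freq = allele_freq, genotype_or = genotype_or,
              lifestyle_prevalence = lifestyle_prevalence,
              lifestyle_or = lifestyle_or,
              interaction_reri_target = interaction_reri_target,
              baseline_prevalence = baseline_prevalence,
              bp_model = bp_model,
              covariate_distributions = covariate_distributions)

  if (cfg$n_subjects < 0) stop("n_subjects must be non-negative", call. = FALSE)
  if (length(cfg$allele_freq) != 13 || is.null(names(cfg$allele_freq)) ||
      !setequal(names(cfg$allele_freq), snps))
    stop("allele_freq must name all 13 SNPs", call. = FALSE)
  if (any(cfg$allele_freq <= 0 | cfg$allele_freq >= 1))
    stop("allele frequencies must lie in (0, 1)", call. = FALSE)
  if (any(cfg$genotype_or$het_or <= 0) || any(cfg$genotype_or$hom_or <= 0) ||
      any(cfg$lifestyle_or <= 0))
    stop("odds ratios must be positive", call. = FALSE)
  if (any(cfg$lifestyle_prevalence < 0 | cfg$lifestyle_prevalence > 1))
    stop("lifestyle prevalences must lie in [0, 1]", call. = FALSE)
  if (cfg$baseline_prevalence <= 0 || cfg$baseline_prevalence >= 1)
    stop("baseline_prevalence must lie in (0, 1)", call. = FALSE)
  for (o in c("sbp", "dbp"))
    if (cfg$bp_model[[o]]$resid_sd <= 0)
      stop("residual SDs must be positive", call. = FALSE)
  structure(cfg, class = "gl_sim_config")
}

# ---- internal draws ----------------------------------------------------

# genotype labels for n subjects at one SNP under Hardy-Weinberg
.draw_genotypes <- function(n, p) {
  probs <- c(ref = (1 - p)^2, het = 2 * p * (1 - p), hom = p^2)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# normal truncated above at `upper`, location shifted so the truncated
# mean equals `target_mean` (two fixed-point refinements suffice)
.rnorm_trunc_upper <- function(n, target_mean, sd, upper) {
  mu <- target_mean
  for (i in 1:3) {
    alpha <- (upper - mu) / sd
    mu <- target_mean + sd * stats::dnorm(alpha) / stats::pnorm(alpha)
  }
  u <- stats::runif(n) * stats::pnorm(upper, mu, sd)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mu, sd)
}

# integer scores for 9 items in 0..4 that sum exactly to `target`
.compose_item_scores <- function(target) {
  n <- length(target)
  B <- matrix(stats::rbinom(n * 9L, size = 4L,
                            prob = rep(pmin(pmax(target / 36, 0.02), 0.98), 9L)),
              nrow = n, ncol = 9L)
  d <- target - rowSums(B)
  it <- 0L
  while (any(d != 0) && it < 500L) {
    it <- it + 1L
    rows <- which(d != 0)
    pick <- cbind(rows, sample.int(9L, length(rows), replace = TRUE))
    up <- d[rows] > 0 & B[pick] < 4L
    dn <- d[rows] < 0 & B[pick] > 0L
    B[pick[up, , drop = FALSE]] <- B[pick[up, , drop = FALSE]] + 1L
    B[pick[dn, , drop = FALSE]] <- B[pick[dn, , drop = FALSE]] - 1L
    d[rows[up]] <- d[rows[up]] - 1L
    d[rows[dn]] <- d[rows[dn]] + 1L
  }
  if (any(d != 0)) stop("internal: CHEI composition failed", call. = FALSE)
  B
}

# CHEI targets on the requested side of 17 (observed-range-like support)
.draw_chei_targets <- function(unhealthful) {
  n <- length(unhealthful)
  lo_support <- 3:16;  lo_w <- stats::dnorm(lo_support, 13, 2.8)
  hi_support <- 17:28; hi_w <- stats::dnorm(hi_support, 19, 2.5)
  t <- integer(n)
  t[unhealthful] <- sample(lo_support, sum(unhealthful), TRUE, lo_w)
  t[!unhealthful] <- sample(hi_support, sum(!unhealthful), TRUE, hi_w)
  t
}

.score_to_freq <- function(score, reverse = FALSE) {
  lv <- gl_freq_levels()  # daily ... never == scores 4..0 for beneficial
  if (reverse) lv <- rev(lv)
  lv[5L - score]
}

# product-term coefficient reaching the RERI target, by root-finding on a
# noise-free expectation draw of the linear predictor
.calibrate_interaction <- function(lp0, a, b, target) {
  cells <- function(beta_ab) {
    p <- stats::plogis(lp0 + beta_ab * a * b)
    r <- c(r00 = mean(p[a == 0 & b == 0]), r10 = mean(p[a == 1 & b == 0]),
           r01 = mean(p[a == 0 & b == 1]), r11 = mean(p[a == 1 & b == 1]))
    odds <- r / (1 - r)
    unname(odds["r11"] / odds["r00"] - odds["r10"] / odds["r00"] -
             odds["r01"] / odds["r00"] + 1)
  }
  f <- function(x) cells(x) - target
  out <- tryCatch(stats::uniroot(f, c(-4, 4), tol = 1e-6),
                  error = function(e)
                    stop("calibration error: RERI target unreachable with the configured odds ratios",
                         call. = FALSE))
  out$root
}

# ---- generator ---------------------------------------------------------

#' Generate a seeded synthetic cohort
#'
#' Draws a full cohort table with the statistical structure the analysis
#' pipeline assumes: genotypes per SNP under Hardy-Weinberg at the
#' configured allele frequencies; five binary lifestyle states at the
#' configured unhealthful prevalences, then raw lifestyle variables
#' (food-frequency items composing an exact CHEI on the intended side of
#' the cutoff, BMI from a mixture straddling the healthy band, smoking
#' status and quit-years, IPAQ level, drinks per year) that the scoring
#' classifiers map back onto those states; incident hypertension from a
#' logistic model whose linear predictor sums the per-genotype and
#' per-factor log odds ratios (plus an optional calibrated product term);
#' and follow-up blood pressures from linear shifts plus Gaussian
#' residuals, reconciled with the outcome so that the cohort-table
#' invariant holds: a case whose drawn pressures sit below the cutoffs
#' gets the antihypertensive-medication flag (a treated patient), a
#' non-case whose pressures reached the cutoffs has them redrawn below.
#'
#' Covariates are drawn independently of the exposures, which keeps the
#' analytic expectations of downstream estimators checkable.
#'
#' The drawn latent states are attached as attribute `truth` (data frame
#' with the five unhealthful-state indicators, risk-allele counts, the
#' linear predictor and event probability) for use in parameter-recovery
#' checks; the attribute is not written by [write_cohort()].
#'
#' @param config A [sim_config()].
#' @return A validated cohort data frame of `config$n_subjects` rows.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "gl_sim_config"))
  n <- config$n_subjects
  snps <- gl_snps()
  empty <- function() {
    cols <- gl_cohort_columns()
    df <- as.data.frame(stats::setNames(replicate(length(cols), character(0),
                                                  simplify = FALSE), cols))
    validate_cohort(df)
    df
  }
  if (n == 0) return(empty())

  .with_seed(config$seed, {
    cd <- config$covariate_distributions
    age <- pmin(pmax(stats::rnorm(n, cd$age_mean, cd$age_sd), 18), 79)
    sex <- ifelse(stats::runif(n) < cd$p_male, "male", "female")
    education <- sample(names(cd$education_probs), n, TRUE, cd$education_probs)
    marital <- ifelse(stats::runif(n) < cd$p_married, "married_cohabit", "other")
    income <- sample(names(cd$income_probs), n, TRUE, cd$income_probs)
    family_history <- stats::runif(n) < cd$p_family_history

    geno <- stats::setNames(
      lapply(snps, function(s) .draw_genotypes(n, config$allele_freq[[s]])),
      snps)
    risk_alleles <- Reduce(`+`, lapply(geno, function(g)
      ifelse(g == "hom", 2L, ifelse(g == "het", 1L, 0L))))
    genetic_lp <- numeric(n)
    for (i in seq_along(snps)) {
      g <- geno[[snps[i]]]
      genetic_lp <- genetic_lp +
        log(config$genotype_or$het_or[i]) * (g == "het") +
        log(config$genotype_or$hom_or[i]) * (g == "hom")
    }

    prev <- config$lifestyle_prevalence
    states <- sapply(c("diet", "bmi", "smoking", "activity", "drinking"),
                     function(f) stats::runif(n) < prev[[f]])  # TRUE = unhealthful
    if (n == 1) states <- matrix(states, nrow = 1,
                                 dimnames = list(NULL, c("diet", "bmi", "smoking",
                                                         "activity", "drinking")))
    lifestyle_lp <- drop(states %*% log(config$lifestyle_or[colnames(states)]))

    # raw lifestyle variables consistent with the drawn binary states
    chei_target <- .draw_chei_targets(states[, "diet"])
    B <- .compose_item_scores(chei_target)
    ff <- as.data.frame(stats::setNames(lapply(1:9, function(j)
      .score_to_freq(B[, j], reverse = j == 9L)), paste0("ff_", gl_food_items())))

    bmi <- numeric(n)
    h <- !states[, "bmi"]
    bmi[h] <- pmin(pmax(stats::rnorm(sum(h), 21.3, 1.5), 18.5), 23.9)
    low_tail <- states[, "bmi"] & stats::runif(n) < 0.08
    hi_tail <- states[, "bmi"] & !low_tail
    bmi[low_tail] <- stats::runif(sum(low_tail), 16.0, 18.4)
    bmi[hi_tail] <- pmin(pmax(stats::rnorm(sum(hi_tail), 26.6, 2.1), 24.0), 40)

    smoking <- rep("never", n)
    years_since_quit <- rep(NA_real_, n)
    us <- states[, "smoking"]
    former_recent <- us & stats::runif(n) < 0.15
    smoking[us] <- "current"
    smoking[former_recent] <- "former"
    years_since_quit[former_recent] <- floor(stats::runif(sum(former_recent), 0, 30))
    former_long <- !us & stats::runif(n) < 0.03
    smoking[former_long] <- "former"
    years_since_quit[former_long] <- floor(stats::runif(sum(former_long), 30, 51))

    ipaq <- ifelse(states[, "activity"], "low",
                   ifelse(stats::runif(n) < 0.6, "moderate", "high"))

    drinks <- integer(n)
    ud <- states[, "drinking"]
    drinks[ud] <- pmin(13L + stats::rnbinom(sum(ud), size = 2, mu = 90), 365L)
    light <- !ud & stats::runif(n) < 0.2
    drinks[light] <- sample(1:12, sum(light), replace = TRUE)

    # outcome model
    lp0 <- stats::qlogis(config$baseline_prevalence) + genetic_lp + lifestyle_lp
    beta_ab <- 0
    if (!is.null(config$interaction_reri_target) &&
        config$interaction_reri_target != 0) {
      a <- as.numeric(rowSums(states) >= 2)  # lifestyle score <= 3
      b <- as.numeric(genetic_lp >= stats::median(genetic_lp))
      beta_ab <- .calibrate_interaction(lp0, a, b, config$interaction_reri_target)
      lp0 <- lp0 + beta_ab * a * b
    }
    p_event <- stats::plogis(lp0)
    hypertension <- stats::runif(n) < p_event

    # baseline BP: hypertension-free cohort, so truncated below the cutoffs
    baseline_sbp <- round(.rnorm_trunc_upper(n, config$bp_model$baseline$sbp_mean,
                                             config$bp_model$baseline$sbp_sd, 139.9), 1)
    baseline_dbp <- round(.rnorm_trunc_upper(n, config$bp_model$baseline$dbp_mean,
                                             config$bp_model$baseline$dbp_sd, 89.9), 1)
    swap <- baseline_sbp <= baseline_dbp
    baseline_dbp[swap] <- pmin(baseline_sbp[swap] - 10, 89.9)

    draw_followup <- function(idx) {
      m <- length(idx)
      shifts <- function(bm) drop(states[idx, , drop = FALSE] %*%
                                    bm$per_unhealthful[colnames(states)]) +
        bm$per_allele * risk_alleles[idx] +
        (bm$case_shift %||% 0) * hypertension[idx]
      sbp <- config$bp_model$sbp$intercept +
        config$bp_model$sbp$baseline_slope * baseline_sbp[idx] +
        shifts(config$bp_model$sbp) +
        stats::rnorm(m, 0, config$bp_model$sbp$resid_sd)
      dbp <- config$bp_model$dbp$intercept +
        config$bp_model$dbp$baseline_slope * baseline_dbp[idx] +
        shifts(config$bp_model$dbp) +
        stats::rnorm(m, 0, config$bp_model$dbp$resid_sd)
      list(sbp = round(sbp, 1), dbp = round(dbp, 1))
    }
    fu <- draw_followup(seq_len(n))
    followup_sbp <- fu$sbp; followup_dbp <- fu$dbp

    # reconcile with the outcome draw (see description)
    med <- rep(FALSE, n)
    for (it in 1:200) {
      over <- !hypertension & (followup_sbp >= 140 | followup_dbp >= 90)
      bad_order <- followup_sbp <= followup_dbp
      redo <- which(over | bad_order)
      if (length(redo) == 0) break
      rf <- draw_followup(redo)
      followup_sbp[redo] <- rf$sbp
      followup_dbp[redo] <- rf$dbp
    }
    clamp <- which(!hypertension & (followup_sbp >= 140 | followup_dbp >= 90))
    followup_sbp[clamp] <- pmin(followup_sbp[clamp], 139.9)
    followup_dbp[clamp] <- pmin(followup_dbp[clamp], 89.9)
    bad <- which(followup_sbp <= followup_dbp)
    followup_dbp[bad] <- followup_sbp[bad] - 10
    med[hypertension & followup_sbp < 140 & followup_dbp < 90] <- TRUE

    cohort <- data.frame(
      subject_id = sprintf("S%06d", seq_len(n)),
      age = round(age, 1), sex = sex, education = education, marital = marital,
      income = income, family_history_htn = family_history,
      antihypertensive_med = med,
      baseline_sbp = baseline_sbp, baseline_dbp = baseline_dbp,
      followup_sbp = followup_sbp, followup_dbp = followup_dbp,
      hypertension = hypertension,
      stringsAsFactors = FALSE)
    cohort <- cbind(cohort, ff)
    cohort$bmi <- round(bmi, 1)
    cohort$smoking <- smoking
    cohort$years_since_quit <- years_since_quit
    cohort$ipaq_level <- ipaq
    cohort$drinks_per_year <- drinks
    for (s in snps) cohort[[s]] <- geno[[s]]
    cohort <- cohort[, gl_cohort_columns()]
    validate_cohort(cohort)
    truth <- as.data.frame(states)
    names(truth) <- paste0("unhealthful_", names(truth))
    truth$risk_alleles <- risk_alleles
    truth$genetic_lp <- genetic_lp
    truth$lp <- lp0
    truth$p_event <- p_event
    for (s in snps) truth[[paste0(s, "_geno")]] <- geno[[s]]
    attr(cohort, "truth") <- truth
    attr(cohort, "interaction_coef") <- beta_ab
    cohort
  })
}

#' Realized marginal distributions of a cohort
#'
#' Summarizes a cohort the way a characteristics table would: per-factor
#' unhealthful prevalence (under the default classification rules),
#' genotype frequencies per SNP, incidence, and blood pressure means/SDs.
#'
#' @param cohort A cohort data frame.
#' @param config An [analysis_config()] supplying the classification
#'   rules.
#' @return List with elements `n`, `incidence`, `unhealthful_prevalence`
#'   (named, proportions), `bp` (means and SDs of the four pressures) and
#'   `genotype_freq` (13 x 3 matrix of proportions).
#' @export
marginal_report <- function(cohort, config = analysis_config()) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  prof <- lifestyle_profile(cohort, config)
  unh <- c(diet = mean(!prof$diet_healthful),
           bmi = mean(!prof$bmi_healthful),
           smoking = mean(!prof$smoking_healthful),
           activity = mean(!prof$activity_healthful),
           drinking = mean(!prof$drinking_healthful))
  gf <- t(sapply(gl_snps(), function(s)
    prop.table(table(factor(cohort[[s]], levels = gl_genotype_levels())))))
  bp <- sapply(c("baseline_sbp", "baseline_dbp", "followup_sbp", "followup_dbp"),
               function(cl) c(mean = mean(cohort[[cl]]), sd = stats::sd(cohort[[cl]])))
  list(n = nrow(cohort),
       incidence = mean(as.logical(cohort$hypertension)),
       unhealthful_prevalence = unh,
       lifestyle_score_dist = prop.table(table(factor(prof$lifestyle_score, levels = 0:5))),
       bp = bp,
       genotype_freq = gf)
}
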