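# build a one-row food-frequency table
ff_row <- function(beneficial = "weekly", red_meat = "weekly") {
  ff <- as.data.frame(as.list(stats::setNames(rep(beneficial, 9),
                                              paste0("ff_", gl_food_items()))),
                      stringsAsFactors = FALSE)
  ff$ff_red_meat <- red_meat
  ff
}

# independent oracle: per-item lookup summed by hand
chei_oracle <- function(freqs) {
  pts <- c(daily = 4, weekly = 3, monthly = 2, annually = 1, never = 0)
  sum(pts[freqs[1:8]]) + (4 - pts[[freqs[9]]])
}

test_that("CHEI bounds and hand-summed values", {
  expect_equal(chei_score(ff_row("daily", "never")), 36L)
  expect_equal(chei_score(ff_row("never", "daily")), 0L)
  # 8 beneficial weekly (24) + reverse-scored weekly red meat (1)
  expect_equal(chei_score(ff_row("weekly", "weekly")), 25L)
  expect_equal(chei_score(ff_row("monthly", "annually")), 8L * 2L + 3L)
  expect_error(chei_score(ff_row("sometimes")), "unknown frequency")
})

test_that("CHEI matches the lookup oracle and is monotone and symmetric", {
  lv <- c("daily", "weekly", "monthly", "annually", "never")
  set.seed(11)
  for (i in 1:50) {
    freqs <- sample(lv, 9, replace = TRUE)
    ff <- as.data.frame(as.list(stats::setNames(freqs, paste0("ff_", gl_food_items()))))
    expect_equal(chei_score(ff), as.integer(chei_oracle(freqs)))
    # permuting the 8 beneficial foods leaves the score unchanged
    perm <- freqs
    perm[1:8] <- sample(freqs[1:8])
    ffp <- as.data.frame(as.list(stats::setNames(perm, paste0("ff_", gl_food_items()))))
    expect_equal(chei_score(ffp), chei_score(ff))
    # raising a beneficial food's frequency never lowers the score;
    # raising red meat frequency never raises it
    j <- sample(1:8, 1)
    k <- match(freqs[j], lv)
    if (k > 1) {
      up <- freqs; up[j] <- lv[k - 1]
      ffu <- as.data.frame(as.list(stats::setNames(up, paste0("ff_", gl_food_items()))))
      expect_gte(chei_score(ffu), chei_score(ff))
    }
    k9 <- match(freqs[9], lv)
    if (k9 > 1) {
      up <- freqs; up[9] <- lv[k9 - 1]
      ffu <- as.data.frame(as.list(stats::setNames(up, paste0("ff_", gl_food_items()))))
      expect_lte(chei_score(ffu), chei_score(ff))
    }
  }
})

test_that("factor classifiers honor their documented boundaries", {
  cfg <- analysis_config()
  expect_true(classify_diet(17, config = cfg))
  expect_false(classify_diet(16, config = cfg))
  # empirical top-40% mode, brute-force percentile on a 10-value list
  cfg_e <- analysis_config(chei_cutoff_mode = "empirical_top40pct")
  expect_true(classify_diet(17, cohort_chei = 10:19, config = cfg_e))
  expect_false(classify_diet(12, cohort_chei = 10:19, config = cfg_e))
  expect_error(classify_diet(17, cohort_chei = integer(0), config = cfg_e), "cohort")

  expect_true(classify_bmi(18.5))
  expect_false(classify_bmi(18.4))
  expect_true(classify_bmi(23.9))
  expect_false(classify_bmi(24.0))
  expect_false(classify_bmi(24.5))
  expect_true(classify_bmi(24.5, analysis_config(bmi_rule = "sensitivity25")))
  expect_false(classify_bmi(25.0, analysis_config(bmi_rule = "sensitivity25")))
  expect_error(classify_bmi(-1), "positive")

  expect_true(classify_smoking("never"))
  expect_true(classify_smoking("former", 30))
  expect_false(classify_smoking("former", 29))
  expect_false(classify_smoking("current"))
  expect_error(classify_smoking("former", NA), "years_since_quit")
  expect_error(classify_smoking("sometimes"), "unknown")

  expect_true(classify_activity("moderate"))
  expect_true(classify_activity("high"))
  expect_false(classify_activity("low"))
  expect_error(classify_activity("none"), "unknown")

  expect_true(classify_drinking(0))
  expect_true(classify_drinking(12))
  expect_false(classify_drinking(13))
  expect_error(classify_drinking(-1), "negative")
})

test_that("lifestyle score counts healthful factors and groups 0-1/2-3/4-5", {
  co <- make_tiny_cohort()
  # subject 1: diet CHEI 25 (healthful), BMI 22.1 (h), never smoker (h),
  # moderate activity (h), 0 drinks (h) -> score 5
  prof <- lifestyle_profile(co)
  expect_equal(prof$lifestyle_score[1], 5)
  expect_equal(as.character(prof$lifestyle_group[1]), "healthful")
  # subject 2: diet h, BMI 26.8 (u), former 35y (h), low activity (u),
  # 20 drinks (u) -> score 2, intermediate
  expect_equal(prof$lifestyle_score[2], 2)
  expect_equal(as.character(prof$lifestyle_group[2]), "intermediate")
  # subject 4: diet h, BMI 24.9 (u), never (h), low (u), 100 drinks (u) -> 2
  expect_equal(prof$lifestyle_score[4], 2)
  # score equals the sum of the five indicators for every subject
  expect_equal(prof$lifestyle_score,
               prof$diet_healthful + prof$bmi_healthful + prof$smoking_healthful +
                 prof$activity_healthful + prof$drinking_healthful)
  expect_equal(as.character(lifestyle_group(c(0, 1, 2, 3, 4, 5))),
               c("unhealthful", "unhealthful", "intermediate", "intermediate",
                 "healthful", "healthful"))
})

test_that("genotype effect values reproduce closed-form 2x3 table log-odds-ratios", {
  # counts: ref 20/100 events, het 30/80, hom 20/40
  g <- c(rep("ref", 100), rep("het", 80), rep("hom", 40))
  y <- c(rep(c(TRUE, FALSE), c(20, 80)), rep(c(TRUE, FALSE), c(30, 50)),
         rep(c(TRUE, FALSE), c(20, 20)))
  co <- data.frame(hypertension = y)
  for (s in gl_snps()) co[[s]] <- g
  m <- estimate_genotype_effects(co)
  or_het <- (30 / 50) / (20 / 80)
  or_hom <- (20 / 20) / (20 / 80)
  expect_equal(m$het_effect, rep(log(or_het), 13), tolerance = 1e-6)
  expect_equal(m$hom_effect, rep(log(or_hom), 13), tolerance = 1e-6)
  expect_equal(m$n_used, rep(220L, 13))
})

test_that("degenerate loci get zero effects with a warning", {
  g <- rep("ref", 50)
  y <- rep(c(TRUE, FALSE), 25)
  co <- data.frame(hypertension = y)
  for (s in gl_snps()) co[[s]] <- g
  co[[gl_snps()[1]]] <- c(rep("het", 25), rep("ref", 25))  # keep one usable
  w <- capture_warnings(m <- estimate_genotype_effects(co))
  expect_true(any(grepl("fewer than 2", w)))
  expect_equal(m$hom_effect, rep(0, 13))
  expect_true(all(m$note[-1] == "degenerate"))
})

test_that("GRS is the sum of genotype effect values", {
  model <- data.frame(snp = gl_snps(),
                      het_effect = seq(0.01, 0.13, by = 0.01),
                      hom_effect = seq(0.02, 0.26, by = 0.02))
  geno <- as.data.frame(as.list(stats::setNames(rep("ref", 13), gl_snps())))
  expect_equal(compute_grs(geno, model), 0)
  geno2 <- geno; geno2$rs2107595 <- "het"  # snp 6, effect 0.06
  expect_equal(compute_grs(geno2, model), 0.06)
  # hand-listed mixed genotypes: brute-force summation oracle
  labels <- c("het", "ref", "hom", "hom", "ref", "het", "ref", "hom", "het",
              "ref", "het", "hom", "ref")
  geno3 <- as.data.frame(as.list(stats::setNames(labels, gl_snps())))
  expected <- sum(ifelse(labels == "het", model$het_effect,
                         ifelse(labels == "hom", model$hom_effect, 0)))
  expect_equal(compute_grs(geno3, model), expected)
  # additivity: flipping one SNP changes the sum by that SNP's effect difference
  geno4 <- geno3; geno4$rs7136259 <- "het"  # snp 4 was hom
  expect_equal(compute_grs(geno4, model) - compute_grs(geno3, model),
               model$het_effect[4] - model$hom_effect[4])
  # missing genotype propagates NA; unknown label errors
  geno5 <- geno3; geno5$rs1378942 <- NA
  expect_true(is.na(compute_grs(geno5, model)))
  geno6 <- geno3; geno6$rs1378942 <- "AB"
  expect_error(compute_grs(geno6, model), "unknown genotype")
})

test_that("tertile assignment partitions evenly with stable tie handling", {
  g <- assign_grs_groups(1:9)
  expect_equal(as.character(g), rep(c("low", "intermediate", "high"), each = 3))
  expect_equal(attr(g, "cutpoints"), unname(stats::quantile(1:9, c(1 / 3, 2 / 3))))

  g2 <- assign_grs_groups(c(0.4, 1.7))
  expect_equal(as.character(g2), c("low", "high"))

  expect_warning(g3 <- assign_grs_groups(rep(2.5, 6)), "identical")
  expect_equal(as.character(g3), rep("low", 6))

  # heavy ties: sizes still differ by at most 2
  set.seed(3)
  for (i in 1:20) {
    x <- sample(c(0, 0, 0, 1, 1, 2), 60, replace = TRUE)
    tab <- table(assign_grs_groups(x))
    expect_lte(max(tab) - min(tab), 2)
  }
  # mean GRS is non-decreasing across groups
  set.seed(4)
  x <- rnorm(500)
  mg <- tapply(x, assign_grs_groups(x), mean)
  expect_true(all(diff(mg) > 0))
  # NA scores yield NA groups
  gna <- assign_grs_groups(c(1, NA, 3, 2))
  expect_true(is.na(gna[2]) && !anyNA(gna[-2]))
})

test_that("score_cohort appends scores and excludes incomplete genotypes from GRS", {
  co <- make_tiny_cohort()
  expect_message(sc <- suppressWarnings(score_cohort(co)), "1 subject")
  expect_true(all(c("chei", "lifestyle_score", "lifestyle_group", "grs",
                    "grs_group") %in% names(sc)))
  expect_true(is.na(sc$grs[3]))  # missing rs1275988
  expect_s3_class(attr(sc, "grs_model"), "grs_model")
})
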