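# hand-written 4-subject cohort covering both outcome routes and a
# missing genotype; all fields valid by construction
make_tiny_cohort <- function() {
  ff <- as.data.frame(
    matrix("weekly", nrow = 4, ncol = 9,
           dimnames = list(NULL, paste0("ff_", gl_food_items()))),
    stringsAsFactors = FALSE)
  co <- data.frame(
    subject_id = c("A1", "A2", "A3", "A4"),
    age = c(45.2, 60.1, 38.0, 52.5),
    sex = c("male", "female", "female", "male"),
    education = c("junior", "primary_or_below", "senior_or_above", "junior"),
    marital = c("married_cohabit", "married_cohabit", "other", "married_cohabit"),
    income = c("lt1000", "lt1000", "1000to2999", "ge3000"),
    family_history_htn = c(TRUE, FALSE, FALSE, TRUE),
    antihypertensive_med = c(FALSE, TRUE, FALSE, FALSE),
    baseline_sbp = c(118, 126, 110, 132),
    baseline_dbp = c(76, 82, 70, 85),
    followup_sbp = c(121, 130, 112, 145),
    followup_dbp = c(78, 84, 72, 92),
    hypertension = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  co <- cbind(co, ff)
  co$bmi <- c(22.1, 26.8, 19.4, 24.9)
  co$smoking <- c("never", "former", "current", "never")
  co$years_since_quit <- c(NA, 35, NA, NA)
  co$ipaq_level <- c("moderate", "low", "high", "low")
  co$drinks_per_year <- c(0, 20, 5, 100)
  for (s in gl_snps()) co[[s]] <- c("ref", "het", "hom", "ref")
  co$rs1275988[3] <- NA
  co[, gl_cohort_columns()]
}

# expand a 2x2 table (a = exposed events, b = exposed non-events,
# c = unexposed events, d = unexposed non-events) into subject-level
# outcome / exposure vectors
expand_2x2 <- function(a, b, c, d) {
  list(y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
       x = c(rep(1, a + b), rep(0, c + d)))
}

# minimal scored-cohort data frame for the epi / models / interaction
# modules, from per-subject vectors
make_scored <- function(lifestyle_score, hypertension, grs = NULL,
                        grs_group = NULL, followup_sbp = NULL,
                        followup_dbp = NULL) {
  n <- length(lifestyle_score)
  df <- data.frame(
    subject_id = sprintf("X%03d", seq_len(n)),
    lifestyle_score = lifestyle_score,
    lifestyle_group = lifestyle_group(lifestyle_score),
    hypertension = as.logical(hypertension),
    stringsAsFactors = FALSE)
  df$grs <- if (is.null(grs)) stats::runif(n) else grs
  df$grs_group <- if (is.null(grs_group))
    assign_grs_groups(df$grs) else factor(grs_group, levels = gl_grs_groups())
  df$followup_sbp <- if (is.null(followup_sbp)) 120 + 5 * df$hypertension else followup_sbp
  df$followup_dbp <- if (is.null(followup_dbp)) 75 + 3 * df$hypertension else followup_dbp
  df
}
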