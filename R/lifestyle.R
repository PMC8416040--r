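#' Diet-quality (CHEI) score from food frequencies
#'
#' Each of the nine food-frequency items contributes 0-4 points. The eight
#' beneficial foods score daily = 4, weekly = 3, monthly = 2, annually = 1,
#' never = 0; red meat is reverse-scored (daily = 0 ... never = 4). The
#' theoretical range is therefore 0-36.
#'
#' @param food_freq A data frame (or named list) with one column per item
#'   in [gl_food_items()], columns named `ff_<item>` or `<item>`, each a
#'   character vector of frequency labels.
#' @return Integer vector of CHEI scores, one per row.
#' @export
chei_score <- function(food_freq) {
  food_freq <- as.data.frame(food_freq, stringsAsFactors = FALSE)
  items <- gl_food_items()
  cols <- ifelse(paste0("ff_", items) %in% names(food_freq),
                 paste0("ff_", items), items)
  missing <- items[!(cols %in% names(food_freq))]
  if (length(missing) > 0)
    stop("missing food-frequency item(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  beneficial <- c(daily = 4L, weekly = 3L, monthly = 2L, annually = 1L, never = 0L)
  total <- integer(nrow(food_freq))
  for (i in seq_along(items)) {
    v <- food_freq[[cols[i]]]
    bad <- which(!(v %in% names(beneficial)))
    if (length(bad) > 0)
      stop(sprintf("unknown frequency label in item '%s' (rows %s)", items[i],
                   paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
    pts <- beneficial[v]
    if (items[i] == "red_meat") pts <- 4L - pts
    total <- total + as.integer(pts)
  }
  total
}

#' Binary lifestyle-factor classifications
#'
#' Each factor is dichotomized into healthful (`TRUE`) and unhealthful
#' (`FALSE`):
#' * diet: CHEI at or above the cutoff (fixed threshold 17 by default, or
#'   the cohort's empirical 60th percentile);
#' * BMI: within \[18.5, 24) kg/m2 (upper cutoff 25 under the sensitivity
#'   rule);
#' * smoking: never smoked, or quit 30 or more years ago;
#' * physical activity: IPAQ moderate or high;
#' * drinking: at most 12 drinking occasions in the last year.
#'
#' @param chei Integer CHEI score(s).
#' @param cohort_chei All CHEI scores of the cohort; required in empirical
#'   mode, ignored otherwise.
#' @param config An [analysis_config()].
#' @return Logical vector, `TRUE` = healthful.
#' @name classify
NULL

#' @rdname classify
#' @export
classify_diet <- function(chei, cohort_chei = NULL, config = analysis_config()) {
  if (config$chei_cutoff_mode == "fixed_threshold") {
    chei >= config$chei_fixed_threshold
  } else {
    if (is.null(cohort_chei) || length(cohort_chei) == 0)
      stop("empirical diet cutoff needs the cohort's CHEI scores", call. = FALSE)
    chei >= stats::quantile(cohort_chei, 0.60, type = 7, names = FALSE)
  }
}

#' @rdname classify
#' @param bmi Body-mass index, kg/m2.
#' @export
classify_bmi <- function(bmi, config = analysis_config()) {
  if (any(bmi <= 0)) stop("BMI must be positive", call. = FALSE)
  upper <- if (config$bmi_rule == "sensitivity25") 25.0 else 24.0
  bmi >= 18.5 & bmi < upper
}

#' @rdname classify
#' @param status Smoking status, one of `"never"`, `"former"`, `"current"`.
#' @param years_since_quit Years since cessation; required for former
#'   smokers.
#' @export
classify_smoking <- function(status, years_since_quit = NA_real_) {
  bad <- which(!(status %in% gl_smoking_levels()))
  if (length(bad) > 0)
    stop("unknown smoking status (rows ",
         paste(utils::head(bad, 10), collapse = ", "), ")", call. = FALSE)
  years_since_quit <- rep_len(years_since_quit, length(status))
  if (any(status == "former" & is.na(years_since_quit)))
    stop("former smokers require years_since_quit", call. = FALSE)
  status == "never" | (status == "former" & years_since_quit >= 30)
}

#' @rdname classify
#' @param ipaq_level IPAQ physical activity level, `"low"`, `"moderate"`
#'   or `"high"`.
#' @export
classify_activity <- function(ipaq_level) {
  bad <- which(!(ipaq_level %in% gl_ipaq_levels()))
  if (length(bad) > 0)
    stop("unknown IPAQ level (rows ",
         paste(utils::head(bad, 10), collapse = ", "), ")", call. = FALSE)
  ipaq_level %in% c("moderate", "high")
}

#' @rdname classify
#' @param drinks_per_year Drinking occasions in the last year.
#' @export
classify_drinking <- function(drinks_per_year) {
  if (any(drinks_per_year < 0)) stop("drink count cannot be negative", call. = FALSE)
  drinks_per_year <= 12
}

#' Five-factor lifestyle profile
#'
#' Applies the five classifiers to every subject, counts healthful factors
#' into an integer score 0-5 and assigns the three-level lifestyle group:
#' scores 0-1 unhealthful, 2-3 intermediate, 4-5 healthful.
#'
#' @param cohort A validated cohort data frame.
#' @param config An [analysis_config()].
#' @return Data frame with columns `chei`, `diet_healthful`,
#'   `bmi_healthful`, `smoking_healthful`, `activity_healthful`,
#'   `drinking_healthful`, `lifestyle_score`, and `lifestyle_group` (factor
#'   with levels unhealthful < intermediate < healthful).
#' @export
lifestyle_profile <- function(cohort, config = analysis_config()) {
  chei <- chei_score(cohort)
  prof <- data.frame(
    chei = chei,
    diet_healthful = classify_diet(chei, cohort_chei = chei, config = config),
    bmi_healthful = classify_bmi(cohort$bmi, config = config),
    smoking_healthful = classify_smoking(cohort$smoking, cohort$years_since_quit),
    activity_healthful = classify_activity(cohort$ipaq_level),
    drinking_healthful = classify_drinking(cohort$drinks_per_year))
  prof$lifestyle_score <- prof$diet_healthful + prof$bmi_healthful +
    prof$smoking_healthful + prof$activity_healthful + prof$drinking_healthful
  prof$lifestyle_group <- lifestyle_group(prof$lifestyle_score)
  prof
}

#' @rdname lifestyle_profile
#' @param score Integer lifestyle score(s) in 0-5.
#' @export
lifestyle_group <- function(score) {
  stopifnot(all(score %in% 0:5))
  factor(ifelse(score >= 4, "healthful",
                ifelse(score >= 2, "intermediate", "unhealthful")),
         levels = gl_lifestyle_groups())
}
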