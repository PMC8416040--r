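#' Derive incident hypertension from follow-up measurements
#'
#' A subject is classified hypertensive at follow-up when systolic blood
#' pressure is at least 140 mmHg, or diastolic blood pressure is at least
#' 90 mmHg, or the subject reported taking antihypertensive medication
#' within the last two weeks.
#'
#' @param followup_sbp Follow-up systolic blood pressure, mmHg.
#' @param followup_dbp Follow-up diastolic blood pressure, mmHg.
#' @param antihypertensive_med Logical; antihypertensive medication within
#'   two weeks of the follow-up visit.
#' @return Logical vector, `TRUE` for incident hypertension.
#' @examples
#' derive_outcome(140, 80, FALSE)  # TRUE, SBP boundary is inclusive
#' derive_outcome(139, 89, FALSE)  # FALSE
#' derive_outcome(120, 70, TRUE)   # TRUE, medication rule
#' @export
derive_outcome <- function(followup_sbp, followup_dbp, antihypertensive_med) {
  if (any(followup_sbp <= 0, na.rm = TRUE) || any(followup_dbp <= 0, na.rm = TRUE))
    stop("blood pressures must be positive", call. = FALSE)
  stopifnot(is.logical(antihypertensive_med) || all(antihypertensive_med %in% c(0, 1)))
  followup_sbp >= 140 | followup_dbp >= 90 | as.logical(antihypertensive_med)
}

# check one categorical column against its enumeration; returns row indices
# of violations (NA allowed only if na_ok)
.check_enum <- function(x, levels, na_ok = FALSE) {
  bad <- !(x %in% levels)
  if (na_ok) bad <- bad & !is.na(x)
  which(bad)
}

.fail_rows <- function(errors, field, rows, what) {
  if (length(rows) == 0) return(errors)
  c(errors, sprintf("field '%s': %s (rows %s)", field, what,
                    paste(utils::head(rows, 10), collapse = ", ")))
}

#' Validate a cohort table
#'
#' Checks the full schema: required columns, unique subject ids, categorical
#' enumerations, positive pressures with SBP above DBP at both visits, BMI
#' and age ranges, quit-years present for former smokers, and agreement of
#' the recorded `hypertension` flag with [derive_outcome()] applied to the
#' follow-up measurements.
#'
#' @param cohort A data frame following the cohort schema
#'   ([gl_cohort_columns()]).
#' @return The cohort, invisibly, with logical columns coerced to logical.
#'   Throws an error listing every offending field and row otherwise.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(gl_cohort_columns(), names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  for (col in c("family_history_htn", "antihypertensive_med", "hypertension")) {
    v <- cohort[[col]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
    cohort[[col]] <- as.logical(v)
  }
  if (nrow(cohort) == 0) return(invisible(cohort))

  errors <- character()
  if (anyDuplicated(cohort$subject_id))
    errors <- c(errors, sprintf("field 'subject_id': duplicated values (%s)",
      paste(utils::head(unique(cohort$subject_id[duplicated(cohort$subject_id)]), 5),
            collapse = ", ")))

  for (col in c("age", "baseline_sbp", "baseline_dbp", "followup_sbp",
                "followup_dbp", "bmi", "drinks_per_year")) {
    errors <- .fail_rows(errors, col, which(is.na(suppressWarnings(as.numeric(cohort[[col]])))),
                         "not numeric")
    cohort[[col]] <- suppressWarnings(as.numeric(cohort[[col]]))
  }
  if (length(errors) > 0)
    stop("invalid cohort table:\n  ", paste(errors, collapse = "\n  "), call. = FALSE)

  enum_checks <- list(
    sex = gl_sex_levels(), education = gl_education_levels(),
    marital = gl_marital_levels(), income = gl_income_levels(),
    smoking = gl_smoking_levels(), ipaq_level = gl_ipaq_levels())
  for (col in names(enum_checks))
    errors <- .fail_rows(errors, col, .check_enum(cohort[[col]], enum_checks[[col]]),
                         "value outside enumeration")
  for (col in paste0("ff_", gl_food_items()))
    errors <- .fail_rows(errors, col, .check_enum(cohort[[col]], gl_freq_levels()),
                         "unknown frequency label")
  for (col in gl_snps())
    errors <- .fail_rows(errors, col,
                         .check_enum(cohort[[col]], gl_genotype_levels(), na_ok = TRUE),
                         "unknown genotype label")

  errors <- .fail_rows(errors, "baseline_sbp",
                       which(!(cohort$baseline_sbp > cohort$baseline_dbp)),
                       "baseline SBP not above baseline DBP")
  errors <- .fail_rows(errors, "followup_sbp",
                       which(!(cohort$followup_sbp > cohort$followup_dbp)),
                       "follow-up SBP not above follow-up DBP")
  for (col in c("baseline_sbp", "baseline_dbp", "followup_sbp", "followup_dbp"))
    errors <- .fail_rows(errors, col, which(cohort[[col]] <= 0), "non-positive pressure")
  errors <- .fail_rows(errors, "bmi", which(cohort$bmi <= 0), "non-positive BMI")
  errors <- .fail_rows(errors, "drinks_per_year", which(cohort$drinks_per_year < 0),
                       "negative count")
  errors <- .fail_rows(errors, "years_since_quit",
                       which(cohort$smoking == "former" &
                               is.na(suppressWarnings(as.numeric(cohort$years_since_quit)))),
                       "former smoker without years_since_quit")

  ok_bp <- !(cohort$followup_sbp <= 0 | cohort$followup_dbp <= 0)
  recomputed <- rep(NA, nrow(cohort))
  recomputed[ok_bp] <- derive_outcome(cohort$followup_sbp[ok_bp],
                                      cohort$followup_dbp[ok_bp],
                                      cohort$antihypertensive_med[ok_bp])
  errors <- .fail_rows(errors, "hypertension",
                       which(ok_bp & cohort$hypertension != recomputed),
                       "inconsistent with follow-up BP and medication flag")

  if (length(errors) > 0)
    stop("invalid cohort table:\n  ", paste(errors, collapse = "\n  "), call. = FALSE)
  invisible(cohort)
}

#' Read a cohort table from delimited text
#'
#' @param path Path to a delimited text file with a header row naming every
#'   required field (see [gl_cohort_columns()]).
#' @param sep Field delimiter; comma by default, tab accepted.
#' @return A validated cohort data frame.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  cohort <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, na.strings = c("NA", ""),
                              colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(gl_cohort_columns(), names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("age", "baseline_sbp", "baseline_dbp", "followup_sbp",
                "followup_dbp", "bmi", "drinks_per_year", "years_since_quit")) {
    v <- suppressWarnings(as.numeric(cohort[[col]]))
    bad <- which(!is.na(cohort[[col]]) & is.na(v))
    if (length(bad) > 0 && col != "years_since_quit")
      stop(sprintf("unparseable numeric in column '%s' (rows %s)", col,
                   paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
    cohort[[col]] <- v
  }
  cohort <- cohort[, c(gl_cohort_columns(),
                       setdiff(names(cohort), gl_cohort_columns())), drop = FALSE]
  out <- validate_cohort(cohort)
  attr(out, "validated") <- TRUE
  out
}

#' Write a cohort table as delimited text
#'
#' Round-trips losslessly through [read_cohort()]: logical flags are written
#' as `TRUE`/`FALSE`, missing genotypes and quit-years as `NA`.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(cohort, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
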