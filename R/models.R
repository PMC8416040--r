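#' Fitted association model
#'
#' Thin wrappers around maximum-likelihood logistic regression and
#' Gaussian (identity-link) linear regression that validate the design,
#' flag rank deficiency and separation, and return a uniform `gl_fit`
#' object with Wald 95% confidence intervals and exponentiated effects for
#' binary outcomes.
#'
#' @param y Outcome: logical/0-1 for [fit_logistic()], numeric (mmHg) for
#'   [fit_linear()].
#' @param design Data frame (or matrix) of predictors; an intercept is
#'   added internally.
#' @param outcome Label stored in the fit (`"hypertension"`, `"sbp"`,
#'   `"dbp"`, ...).
#' @param model_tag Free-form tag (`"model1"`, `"model2"`, `"model3"`).
#' @return `gl_fit`: list with `coefficients`, `covariance`, `estimates`
#'   (term, estimate = OR or beta, conf.low, conf.high, p.value), `n_used`,
#'   `outcome`, `model_tag`, `family`, and the underlying `fit`.
#' @name gl_fit
NULL

.check_design <- function(design, n_min = 1) {
  design <- as.data.frame(design)
  X <- cbind(`(Intercept)` = 1, as.matrix(
    as.data.frame(lapply(design, as.numeric))))
  if (nrow(X) <= ncol(X) - 1 && n_min > 0)
    stop("more coefficients than observations (n <= p)", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  design
}

# lm/glm wrap non-syntactic column names (e.g. product terms named
# "a:b") in backticks; strip them so callers can address terms verbatim
.clean_terms <- function(x) gsub("`", "", x, fixed = TRUE)

.wald_table <- function(fit, exponentiate) {
  co <- stats::coef(fit)
  names(co) <- .clean_terms(names(co))
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)
  est <- co; lo <- co - z * se; hi <- co + z * se
  if (exponentiate) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
  data.frame(term = names(co), estimate = unname(est),
             conf.low = unname(lo), conf.high = unname(hi),
             p.value = unname(2 * stats::pnorm(-abs(co / se))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname gl_fit
#' @export
fit_logistic <- function(y, design, outcome = "hypertension", model_tag = "model1") {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("outcome has a single class; logistic model undefined", call. = FALSE)
  design <- .check_design(design)
  dat <- cbind(.y = y, design)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  co <- stats::coef(fit)
  names(co) <- .clean_terms(names(co))
  big <- names(co)[!is.na(co) & abs(co) > 15]
  if (!fit$converged || length(big) > 0)
    stop("apparent separation in logistic fit; column(s): ",
         paste(if (length(big)) big else "unknown", collapse = ", "), call. = FALSE)
  V <- stats::vcov(fit)
  dimnames(V) <- lapply(dimnames(V), .clean_terms)
  structure(list(coefficients = co, covariance = V,
                 estimates = .wald_table(fit, exponentiate = TRUE),
                 n_used = length(y), outcome = outcome, model_tag = model_tag,
                 family = "binomial", fit = fit),
            class = "gl_fit")
}

#' @rdname gl_fit
#' @export
fit_linear <- function(y, design, outcome = "sbp", model_tag = "model1") {
  y <- as.numeric(y)
  design <- .check_design(design)
  if (nrow(design) <= ncol(design) + 1)
    stop("more coefficients than observations (n <= p)", call. = FALSE)
  dat <- cbind(.y = y, design)
  fit <- stats::lm(.y ~ ., data = dat)
  co <- stats::coef(fit)
  names(co) <- .clean_terms(names(co))
  # noise-free designs are legitimate here (exactness contract); lm warns
  # that the summary may be unreliable on an essentially perfect fit
  V <- suppressWarnings(stats::vcov(fit))
  dimnames(V) <- lapply(dimnames(V), .clean_terms)
  structure(list(coefficients = co, covariance = V,
                 estimates = suppressWarnings(.wald_table(fit, exponentiate = FALSE)),
                 n_used = length(y), outcome = outcome, model_tag = model_tag,
                 family = "gaussian", fit = fit),
            class = "gl_fit")
}

#' @export
print.gl_fit <- function(x, ...) {
  cat(sprintf("<gl_fit> %s (%s), %s, n = %d\n", x$outcome, x$family,
              x$model_tag, x$n_used))
  print(x$estimates, digits = 4)
  invisible(x)
}

# the medication flag is a component of the incident-hypertension
# definition (medication use implies case status), so including it as a
# covariate in models of that outcome yields tautological quasi-separation;
# it stays in the covariate set for the continuous BP outcomes
.covariates_for_outcome <- function(covariate_set, outcome) {
  if (outcome == "hypertension") setdiff(covariate_set, "antihypertensive_med")
  else covariate_set
}

# dummy-coded covariate design for the configured covariate set
.covariate_design <- function(scored, covariate_set) {
  cols <- list()
  for (cv in covariate_set) {
    v <- scored[[cv]]
    if (cv %in% c("age", "baseline_sbp", "baseline_dbp")) {
      cols[[cv]] <- as.numeric(v)
    } else if (cv %in% c("antihypertensive_med", "family_history_htn")) {
      cols[[cv]] <- as.numeric(v)
    } else {
      levs <- switch(cv, sex = gl_sex_levels(), education = gl_education_levels(),
                     marital = gl_marital_levels(), income = gl_income_levels())
      for (lv in levs[-1]) cols[[paste(cv, lv, sep = "_")]] <- as.numeric(v == lv)
    }
  }
  if (length(cols) == 0) return(NULL)
  as.data.frame(cols, check.names = FALSE)
}

.group_dummies <- function(f, prefix) {
  levs <- levels(f)
  out <- lapply(levs[-1], function(lv) as.numeric(f == lv))
  names(out) <- paste(prefix, levs[-1], sep = "_")
  as.data.frame(out, check.names = FALSE)
}

.outcome_vector <- function(scored, outcome) {
  switch(outcome,
         hypertension = as.numeric(scored$hypertension),
         sbp = as.numeric(scored$followup_sbp),
         dbp = as.numeric(scored$followup_dbp),
         stop("unknown outcome: ", outcome, call. = FALSE))
}

#' Separate associations of lifestyle group and GRS group with outcomes
#'
#' Fits, for each outcome (incident hypertension by logistic regression;
#' follow-up SBP and DBP by Gaussian linear models) and each exposure
#' (lifestyle group, reference unhealthful; GRS group, reference low),
#' three models: `model1` unadjusted, `model2` adjusted for the configured
#' covariates, `model3` additionally mutually adjusted for the other
#' exposure. GRS models use only subjects with complete genotypes.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param config An [analysis_config()].
#' @return Data frame with one row per non-reference exposure level and
#'   model: `outcome`, `exposure`, `model_tag`, `level`, `estimate` (OR or
#'   beta), `conf.low`, `conf.high`, `p.value`, `n_used`; reference rows
#'   carry estimate 1 (OR) or 0 (beta). Contrasts whose exposure level is
#'   absent from the data are flagged with `NA` estimates.
#' @export
separate_associations <- function(scored, config = analysis_config()) {
  out <- list()
  for (outcome in c("hypertension", "sbp", "dbp")) {
    for (exposure in c("lifestyle", "grs")) {
      f <- if (exposure == "lifestyle") scored$lifestyle_group else scored$grs_group
      keep <- !is.na(f)
      if (exposure == "grs") keep <- keep & !is.na(scored$grs)
      dat <- scored[keep, , drop = FALSE]
      fk <- droplevels(factor(f[keep], levels = levels(f)))
      full_levels <- levels(f)
      present <- levels(fk)
      expo_design_all <- .group_dummies(factor(fk, levels = present), exposure)
      cov_design <- .covariate_design(dat, .covariates_for_outcome(config$covariate_set, outcome))
      other <- if (exposure == "lifestyle") dat$grs_group else dat$lifestyle_group
      other_ok <- !is.na(other)
      for (tag in c("model1", "model2", "model3")) {
        design <- expo_design_all
        rows <- rep(TRUE, nrow(dat))
        if (tag %in% c("model2", "model3") && !is.null(cov_design))
          design <- cbind(design, cov_design)
        if (tag == "model3") {
          rows <- other_ok
          design <- cbind(design[rows, , drop = FALSE],
                          .group_dummies(droplevels(other[rows]),
                                         if (exposure == "lifestyle") "grs" else "lifestyle"))
        } else design <- design[rows, , drop = FALSE]
        y <- .outcome_vector(dat[rows, , drop = FALSE], outcome)
        ft <- if (outcome == "hypertension") {
          fit_logistic(y, design, outcome = outcome, model_tag = tag)
        } else {
          fit_linear(y, design, outcome = outcome, model_tag = tag)
        }
        ref_est <- if (outcome == "hypertension") 1 else 0
        tab <- data.frame(outcome = outcome, exposure = exposure, model_tag = tag,
                          level = full_levels, estimate = NA_real_,
                          conf.low = NA_real_, conf.high = NA_real_,
                          p.value = NA_real_, n_used = ft$n_used,
                          stringsAsFactors = FALSE)
        tab$estimate[1] <- ref_est; tab$conf.low[1] <- ref_est; tab$conf.high[1] <- ref_est
        for (lv in present[-1]) {
          term <- paste(exposure, lv, sep = "_")
          row <- ft$estimates[ft$estimates$term == term, ]
          i <- match(lv, full_levels)
          tab$estimate[i] <- row$estimate
          tab$conf.low[i] <- row$conf.low
          tab$conf.high[i] <- row$conf.high
          tab$p.value[i] <- row$p.value
        }
        out[[length(out) + 1]] <- tab
      }
    }
  }
  do.call(rbind, out)
}

#' Joint 3x3 gene-lifestyle effect grid
#'
#' One model per outcome with eight dummy variables for the non-reference
#' cells of the GRS-group-by-lifestyle-group grid, relative to the
#' low-GRS / healthful-lifestyle cell, plus the configured covariates.
#' Cells with no subjects (or, for hypertension, no outcome variation) are
#' flagged sparse and omitted from the model.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param config An [analysis_config()].
#' @param adjusted Adjust for `config$covariate_set` (default) or fit the
#'   crude grid.
#' @return Object of class `joint_grid`: data frame with one row per cell
#'   (`grs_group`, `lifestyle_group`, `n`, `events`) and, per outcome,
#'   `or`/`beta` estimates with confidence limits; reference cell has OR 1
#'   and beta 0; sparse cells carry `NA`.
#' @export
joint_effect_grid <- function(scored, config = analysis_config(), adjusted = TRUE) {
  keep <- !is.na(scored$grs_group) & !is.na(scored$lifestyle_group)
  dat <- scored[keep, , drop = FALSE]
  cell <- interaction(dat$grs_group, dat$lifestyle_group, sep = ":", drop = FALSE)
  ref <- "low:healthful"
  cells <- as.vector(outer(gl_grs_groups(), gl_lifestyle_groups(), paste, sep = ":"))
  grid <- data.frame(cell = cells, stringsAsFactors = FALSE)
  grid$grs_group <- sub(":.*", "", cells)
  grid$lifestyle_group <- sub(".*:", "", cells)
  grid$n <- as.integer(table(factor(cell, levels = cells))[cells])
  grid$events <- as.integer(tapply(as.numeric(dat$hypertension),
                                   factor(cell, levels = cells), sum)[cells])
  grid$events[is.na(grid$events)] <- 0L
  grid$sparse <- grid$n == 0

  usable <- cells[!grid$sparse]
  dummies <- as.data.frame(lapply(setdiff(usable, ref),
                                  function(cl) as.numeric(cell == cl)),
                           check.names = FALSE)
  names(dummies) <- paste0("cell_", setdiff(usable, ref))

  for (outcome in c("hypertension", "sbp", "dbp")) {
    cov_design <- if (adjusted)
      .covariate_design(dat, .covariates_for_outcome(config$covariate_set, outcome))
    else NULL
    design <- if (is.null(cov_design)) dummies else cbind(dummies, cov_design)
    y <- .outcome_vector(dat, outcome)
    ft <- if (outcome == "hypertension") {
      fit_logistic(y, design, outcome = outcome, model_tag = "joint")
    } else {
      fit_linear(y, design, outcome = outcome, model_tag = "joint")
    }
    est_name <- if (outcome == "hypertension") "or" else "beta"
    pre <- if (outcome == "hypertension") "or" else paste0("beta_", outcome)
    ref_val <- if (outcome == "hypertension") 1 else 0
    grid[[pre]] <- NA_real_
    grid[[paste0(pre, "_low")]] <- NA_real_
    grid[[paste0(pre, "_high")]] <- NA_real_
    grid[grid$cell == ref, pre] <- ref_val
    grid[grid$cell == ref, paste0(pre, c("_low", "_high"))] <- ref_val
    for (cl in setdiff(usable, ref)) {
      row <- ft$estimates[ft$estimates$term == paste0("cell_", cl), ]
      if (nrow(row) == 1) {
        i <- match(cl, grid$cell)
        grid[i, pre] <- row$estimate
        grid[i, paste0(pre, "_low")] <- row$conf.low
        grid[i, paste0(pre, "_high")] <- row$conf.high
      }
    }
  }
  structure(grid, class = c("joint_grid", "data.frame"), reference = ref,
            adjusted = adjusted)
}

#' @export
print.joint_grid <- function(x, ...) {
  cat(sprintf("<joint_grid> reference cell %s (%s)\n", attr(x, "reference"),
              if (attr(x, "adjusted")) "covariate-adjusted" else "crude"))
  print.data.frame(x, digits = 4)
  invisible(x)
}
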