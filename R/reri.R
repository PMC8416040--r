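#' Dichotomize scores for additive-interaction analysis
#'
#' The additive-interaction contrast uses two binary exposures: lifestyle
#' risk (intermediate and unhealthful groups pooled, versus healthful) and
#' genetic risk (GRS at or above the cohort median — the upper 50th
#' percentile, inclusive — versus below).
#'
#' @param scored A scored cohort from [score_cohort()], or any data frame
#'   with `lifestyle_group` and `grs` columns.
#' @return Data frame with integer columns `lifestyle_risk` and
#'   `genetic_risk` (1 = at risk), `NA` where the GRS is missing; the GRS
#'   median used is attached as attribute `grs_median`.
#' @export
dichotomize_for_reri <- function(scored) {
  stopifnot(all(c("lifestyle_group", "grs") %in% names(scored)))
  med <- stats::median(scored$grs, na.rm = TRUE)
  out <- data.frame(
    lifestyle_risk = as.integer(scored$lifestyle_group %in% c("unhealthful", "intermediate")),
    genetic_risk = ifelse(is.na(scored$grs), NA_integer_,
                          as.integer(scored$grs >= med)))
  attr(out, "grs_median") <- med
  out
}

# RERI point estimate and delta-method variance from three coefficients
# (bA, bB, bAB) and their covariance block
.reri_delta <- function(b, V) {
  or11 <- exp(sum(b)); or10 <- exp(b[1]); or01 <- exp(b[2])
  est <- or11 - or10 - or01 + 1
  grad <- c(or11 - or10, or11 - or01, or11)
  list(estimate = est, se = sqrt(drop(t(grad) %*% V %*% grad)))
}

.reri_terms <- function(fit, term_a, term_b, term_ab) {
  co <- fit$coefficients
  for (tm in c(term_a, term_b, term_ab))
    if (!(tm %in% names(co)))
      stop("fit lacks required term '", tm, "' (both exposures and their product are needed)",
           call. = FALSE)
  idx <- match(c(term_a, term_b, term_ab), names(co))
  list(b = unname(co[idx]), V = fit$covariance[idx, idx, drop = FALSE])
}

#' Relative excess risk due to interaction (RERI)
#'
#' For a logistic model containing two binary exposures and their product
#' term, `RERI = OR11 - OR10 - OR01 + 1`, where
#' `OR11 = exp(bA + bB + bAB)`. RERI > 0 indicates super-additive
#' (positive) interaction on the risk scale, RERI < 0 sub-additive, and
#' RERI = 0 exact additivity of risks. Odds ratios stand in for risk
#' ratios, the usual approximation for uncommon outcomes. The default
#' confidence interval is the delta method on the gradient of RERI in
#' `(bA, bB, bAB)`; a seeded subject-resampling bootstrap is available.
#'
#' For a linear (mean-difference) model the additive-interaction contrast
#' `b11 - b10 - b01` collapses to the product-term coefficient, so
#' [reri_continuous()] reports that coefficient with its Wald interval.
#'
#' @param fit A `gl_fit` containing coefficients for both exposures and
#'   their product.
#' @param term_a,term_b,term_ab Coefficient names of exposure A, exposure
#'   B and the product term.
#' @param method `"delta"` or `"bootstrap"` (binary outcome only).
#' @param data,design_fun Required for the bootstrap: the analysis data
#'   frame and a function `design_fun(data)` returning `list(y, design)`
#'   for refitting.
#' @param reps,seed Bootstrap replicates and seed.
#' @return Object of class `reri_result`: `estimate`, `ci_low`, `ci_high`,
#'   `method`, `outcome`.
#' @export
reri_binary <- function(fit, term_a = "lifestyle_risk", term_b = "genetic_risk",
                        term_ab = "lifestyle_risk:genetic_risk",
                        method = c("delta", "bootstrap"),
                        data = NULL, design_fun = NULL, reps = 500L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "gl_fit"))
  if (fit$family != "binomial")
    stop("reri_binary expects a logistic fit; use reri_continuous for linear models",
         call. = FALSE)
  tm <- .reri_terms(fit, term_a, term_b, term_ab)
  d <- .reri_delta(tm$b, tm$V)
  z <- stats::qnorm(0.975)
  res <- list(estimate = d$estimate, ci_low = d$estimate - z * d$se,
              ci_high = d$estimate + z * d$se, method = "delta",
              outcome = fit$outcome)
  if (method == "bootstrap") {
    if (is.null(data) || is.null(design_fun))
      stop("bootstrap RERI needs `data` and `design_fun`", call. = FALSE)
    boots <- .with_seed(seed, vapply(seq_len(reps), function(i) {
      idx <- sample.int(nrow(data), replace = TRUE)
      yd <- design_fun(data[idx, , drop = FALSE])
      bfit <- tryCatch(fit_logistic(yd$y, yd$design, outcome = fit$outcome),
                       error = function(e) NULL)
      if (is.null(bfit)) return(NA_real_)
      btm <- tryCatch(.reri_terms(bfit, term_a, term_b, term_ab),
                      error = function(e) NULL)
      if (is.null(btm)) return(NA_real_)
      .reri_delta(btm$b, btm$V)$estimate
    }, numeric(1)))
    qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    res$ci_low <- qs[1]; res$ci_high <- qs[2]; res$method <- "bootstrap"
  }
  structure(res, class = "reri_result")
}

#' @rdname reri_binary
#' @export
reri_continuous <- function(fit, term_a = "lifestyle_risk", term_b = "genetic_risk",
                            term_ab = "lifestyle_risk:genetic_risk") {
  stopifnot(inherits(fit, "gl_fit"))
  if (fit$family != "gaussian")
    stop("reri_continuous expects a linear fit", call. = FALSE)
  tm <- .reri_terms(fit, term_a, term_b, term_ab)
  b_ab <- tm$b[3]
  se <- sqrt(tm$V[3, 3])
  z <- stats::qnorm(0.975)
  structure(list(estimate = unname(b_ab), ci_low = unname(b_ab - z * se),
                 ci_high = unname(b_ab + z * se), method = "delta",
                 outcome = fit$outcome),
            class = "reri_result")
}

#' @export
print.reri_result <- function(x, ...) {
  cat(sprintf("RERI (%s, %s CI): %.3f (%.3f, %.3f)\n", x$outcome, x$method,
              x$estimate, x$ci_low, x$ci_high))
  invisible(x)
}

#' Three-outcome RERI panel
#'
#' Fits, for incident hypertension (logistic) and follow-up SBP and DBP
#' (linear), a model with the two dichotomized exposures, their product
#' term and the configured covariates, and extracts the RERI for each.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param config An [analysis_config()]; `reri_ci_method`,
#'   `bootstrap_reps` and `seed` control the binary-outcome interval.
#' @param adjusted Include the configured covariates.
#' @return Data frame with rows hypertension / sbp / dbp and columns
#'   `estimate`, `ci_low`, `ci_high`, `method`.
#' @export
reri_panel <- function(scored, config = analysis_config(), adjusted = TRUE) {
  dich <- dichotomize_for_reri(scored)
  keep <- !is.na(dich$genetic_risk)
  dat <- cbind(scored[keep, , drop = FALSE], dich[keep, , drop = FALSE])
  base_design <- function(d, outcome) {
    des <- data.frame(lifestyle_risk = d$lifestyle_risk,
                      genetic_risk = d$genetic_risk,
                      `lifestyle_risk:genetic_risk` = d$lifestyle_risk * d$genetic_risk,
                      check.names = FALSE)
    cov_design <- if (adjusted)
      .covariate_design(d, .covariates_for_outcome(config$covariate_set, outcome))
    else NULL
    if (is.null(cov_design)) des else cbind(des, cov_design)
  }
  rows <- list()
  for (outcome in c("hypertension", "sbp", "dbp")) {
    y <- .outcome_vector(dat, outcome)
    design <- base_design(dat, outcome)
    if (outcome == "hypertension") {
      ft <- fit_logistic(y, design, outcome = outcome, model_tag = "reri")
      rr <- reri_binary(ft, method = config$reri_ci_method,
                        data = dat,
                        design_fun = function(d)
                          list(y = .outcome_vector(d, "hypertension"),
                               design = base_design(d, "hypertension")),
                        reps = config$bootstrap_reps, seed = config$seed)
    } else {
      ft <- fit_linear(y, design, outcome = outcome, model_tag = "reri")
      rr <- reri_continuous(ft)
    }
    rows[[outcome]] <- data.frame(outcome = outcome, estimate = rr$estimate,
                                  ci_low = rr$ci_low, ci_high = rr$ci_high,
                                  method = rr$method, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
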