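#' Estimate per-genotype effect values for the genetic risk score
#'
#' For each SNP independently, the two non-reference genotypes (`het`,
#' `hom`) are coded as dummy variables against the non-risk homozygote
#' (`ref`) and regressed on the configured outcome — by default a logistic
#' model of incident hypertension, alternatively a linear model of
#' follow-up SBP. The fitted dummy coefficients are the effect values later
#' summed into the GRS. Estimation is unadjusted and single-SNP, one model
#' per locus, in the study sample itself.
#'
#' Degenerate loci (monomorphic, an empty genotype cell, or separation) get
#' effect values of 0 for the affected dummies, with a warning.
#'
#' @param cohort A validated cohort data frame with genotype columns for
#'   every SNP in [gl_snps()].
#' @param config An [analysis_config()]; `grs_effect_outcome` selects the
#'   regression.
#' @return An object of class `grs_model`: a data frame with one row per
#'   SNP (`snp`, `het_effect`, `hom_effect`, `n_used`, `note`), with the
#'   outcome used and cohort size as attributes.
#' @export
estimate_genotype_effects <- function(cohort, config = analysis_config()) {
  snps <- gl_snps()
  outcome_kind <- config$grs_effect_outcome
  y_all <- if (outcome_kind == "hypertension_logistic") {
    as.numeric(cohort$hypertension)
  } else {
    as.numeric(cohort$followup_sbp)
  }
  res <- data.frame(snp = snps, het_effect = 0, hom_effect = 0,
                    n_used = 0L, note = "", stringsAsFactors = FALSE)
  for (i in seq_along(snps)) {
    g <- cohort[[snps[i]]]
    keep <- !is.na(g) & !is.na(y_all)
    g <- g[keep]; y <- y_all[keep]
    res$n_used[i] <- length(y)
    present <- intersect(gl_genotype_levels(), unique(g))
    if (length(present) < 2 || !("ref" %in% present)) {
      res$note[i] <- "degenerate"
      warning(sprintf("SNP %s: fewer than 2 genotype categories with a reference; effects set to 0",
                      snps[i]), call. = FALSE)
      next
    }
    het <- as.numeric(g == "het")
    hom <- as.numeric(g == "hom")
    fit <- tryCatch({
      if (outcome_kind == "hypertension_logistic") {
        stats::glm(y ~ het + hom, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
      } else {
        stats::lm(y ~ het + hom)
      }
    }, error = function(e) NULL)
    co <- if (is.null(fit)) c(het = NA, hom = NA) else stats::coef(fit)[c("het", "hom")]
    # absent category drops its column -> NA coefficient; separation inflates it
    for (dummy in c("het", "hom")) {
      b <- unname(co[dummy])
      target <- paste0(dummy, "_effect")
      if (!(dummy %in% g)) {
        res[[target]][i] <- 0
      } else if (is.null(fit) || is.na(b) || abs(b) > 15) {
        res[[target]][i] <- 0
        res$note[i] <- "degenerate"
        warning(sprintf("SNP %s: unstable %s effect (empty cell or separation); set to 0",
                        snps[i], dummy), call. = FALSE)
      } else {
        res[[target]][i] <- b
      }
    }
  }
  structure(res, class = c("grs_model", "data.frame"),
            outcome = outcome_kind, n_cohort = nrow(cohort))
}

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf("<grs_model> %d SNPs, outcome = %s, cohort n = %d\n",
              nrow(x), attr(x, "outcome"), attr(x, "n_cohort")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Genetic risk score of each subject
#'
#' The GRS is the sum over the 13 loci of the effect value of the subject's
#' genotype: `ref` contributes 0, `het` and `hom` contribute their fitted
#' dummy coefficients. Subjects with any missing genotype get `NA` (they
#' are excluded from GRS-dependent analyses).
#'
#' @param genotypes Data frame holding one column per SNP in `model`.
#' @param model A `grs_model` from [estimate_genotype_effects()], or any
#'   data frame with columns `snp`, `het_effect`, `hom_effect` (e.g.
#'   user-supplied external weights).
#' @return Numeric GRS vector.
#' @export
compute_grs <- function(genotypes, model) {
  stopifnot(all(c("snp", "het_effect", "hom_effect") %in% names(model)))
  missing_snp <- setdiff(model$snp, names(genotypes))
  if (length(missing_snp) > 0)
    stop("genotype column(s) absent: ", paste(missing_snp, collapse = ", "),
         call. = FALSE)
  n <- nrow(as.data.frame(genotypes))
  grs <- numeric(n)
  for (i in seq_len(nrow(model))) {
    g <- genotypes[[model$snp[i]]]
    bad <- which(!is.na(g) & !(g %in% gl_genotype_levels()))
    if (length(bad) > 0)
      stop(sprintf("unknown genotype label for %s (rows %s)", model$snp[i],
                   paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
    grs <- grs + ifelse(is.na(g), NA_real_,
                        ifelse(g == "het", model$het_effect[i],
                               ifelse(g == "hom", model$hom_effect[i], 0)))
  }
  grs
}

#' Percentile risk groups of the genetic risk score
#'
#' Subjects are partitioned into low / intermediate / high risk groups at
#' the empirical tertile cutpoints of the GRS (or at custom percentile
#' cutpoints). Ties at a cutpoint are broken by stable subject order so
#' that group sizes stay as equal as the cutpoints allow. If every GRS is
#' identical the partition is undefined; all subjects are assigned `low`
#' with a warning. `NA` scores yield `NA` groups.
#'
#' @param grs Numeric GRS vector.
#' @param config An [analysis_config()]; `grs_percentiles` gives the
#'   cutpoints when `grs_group_mode = "custom_percentiles"`.
#' @return Factor with levels `low`, `intermediate`, `high` (custom modes
#'   get `g1`, `g2`, ... when more than three groups are requested), with
#'   the numeric cutpoints attached as attribute `cutpoints`.
#' @export
assign_grs_groups <- function(grs, config = analysis_config()) {
  if (length(grs) == 0) stop("empty GRS vector", call. = FALSE)
  probs <- if (config$grs_group_mode == "tertile") c(1 / 3, 2 / 3) else config$grs_percentiles
  k <- length(probs) + 1
  labels <- if (k == 3) gl_grs_groups() else paste0("g", seq_len(k))
  ok <- !is.na(grs)
  out <- factor(rep(NA_character_, length(grs)), levels = labels)
  if (!any(ok)) return(out)
  x <- grs[ok]
  if (length(unique(x)) == 1) {
    warning("all GRS values identical; assigning every subject to the low group",
            call. = FALSE)
    out[ok] <- labels[1]
    attr(out, "cutpoints") <- rep(x[1], length(probs))
    return(out)
  }
  # rank with stable tie-breaking, then cut the ranks at the percentile
  # positions: reproduces value-based tertiles for untied data and keeps
  # group sizes balanced under ties
  r <- rank(x, ties.method = "first")
  breaks <- stats::quantile(r, c(0, probs, 1), type = 7, names = FALSE)
  grp <- cut(r, breaks = breaks, include.lowest = TRUE, labels = labels)
  out[ok] <- as.character(grp)
  attr(out, "cutpoints") <- stats::quantile(x, probs, type = 7, names = FALSE)
  out
}

#' Append lifestyle and genetic scores to a cohort
#'
#' Convenience wrapper running the whole scoring stage: CHEI and the five
#' factor classifications, lifestyle score and group, genotype effect
#' estimation, per-subject GRS and tertile risk group.
#'
#' @param cohort A validated cohort data frame.
#' @param config An [analysis_config()].
#' @param grs_model Optional pre-fitted `grs_model` (e.g. external
#'   weights); fitted in-sample when `NULL`.
#' @return The cohort with scoring columns appended; the fitted `grs_model`
#'   is attached as attribute `grs_model`.
#' @export
score_cohort <- function(cohort, config = analysis_config(), grs_model = NULL) {
  prof <- lifestyle_profile(cohort, config)
  if (is.null(grs_model)) grs_model <- estimate_genotype_effects(cohort, config)
  grs <- compute_grs(cohort[, gl_snps(), drop = FALSE], grs_model)
  scored <- cbind(cohort, prof)
  scored$grs <- grs
  scored$grs_group <- assign_grs_groups(grs, config)
  n_excl <- sum(is.na(grs))
  if (n_excl > 0)
    message(n_excl, " subject(s) with incomplete genotypes excluded from GRS-dependent analyses")
  attr(scored, "grs_model") <- grs_model
  scored
}
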