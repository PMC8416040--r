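#' Exposure / event counts for the lifestyle contrast
#'
#' Subjects with lifestyle scores 0-3 (intermediate and unhealthful
#' groups) form the exposed group; scores 4-5 (healthful) the unexposed
#' group. Optionally restricted to one GRS risk stratum.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param stratum Optional GRS group (`"low"`, `"intermediate"`,
#'   `"high"`); `NULL` for the whole cohort.
#' @return List of class `exposure_counts` with `exposed_events`,
#'   `exposed_total`, `unexposed_events`, `unexposed_total`.
#' @export
tabulate_exposure <- function(scored, stratum = NULL) {
  stopifnot(all(c("lifestyle_score", "hypertension") %in% names(scored)))
  dat <- scored
  if (!is.null(stratum)) {
    stopifnot(stratum %in% levels(scored$grs_group))
    dat <- scored[!is.na(scored$grs_group) & scored$grs_group == stratum, ,
                  drop = FALSE]
  }
  exposed <- dat$lifestyle_score <= 3
  structure(list(
    exposed_events = sum(dat$hypertension[exposed]),
    exposed_total = sum(exposed),
    unexposed_events = sum(dat$hypertension[!exposed]),
    unexposed_total = sum(!exposed)),
    class = "exposure_counts")
}

#' Epidemiological indicator panel for one exposure contrast
#'
#' From incidences in the exposed (`Ie`), unexposed (`Iu`) and total
#' population (`It`):
#' * `rr = Ie / Iu` — relative risk;
#' * `ar = (Ie - Iu) * 100` — attributable risk, percentage points;
#' * `par = It - Iu` — population attributable risk, proportion scale;
#' * `par_pct = (It - Iu) / It * 100` — population attributable risk
#'   percent;
#' * `pfp = (Ie - It) / Ie * 100` — prevented fraction for the population:
#'   the healthful lifestyle is the protective exposure, so the
#'   no-exposure counterfactual incidence is `Ie`;
#' * `morbidities_averted = population_total * (Ie - It)` — events averted
#'   by the current prevalence of the protective exposure.
#'
#' All values are full precision; round only for display.
#'
#' @param counts An `exposure_counts` object (or list with the same
#'   fields).
#' @param population_total,population_events Denominator and events of the
#'   whole population the panel refers to (for a stratified panel, the
#'   stratum's own totals).
#' @return List of class `epi_indicators` with `incidence_total`,
#'   `incidence_exposed`, `incidence_unexposed`, `rr`, `ar`, `par`,
#'   `par_pct`, `pfp`, `morbidities_averted`.
#' @examples
#' compute_indicators(
#'   list(exposed_events = 636, exposed_total = 3046,
#'        unexposed_events = 232, unexposed_total = 1546),
#'   population_total = 4592, population_events = 868)
#' @export
compute_indicators <- function(counts, population_total, population_events) {
  for (f in c("exposed_events", "exposed_total", "unexposed_events", "unexposed_total"))
    if (is.null(counts[[f]])) stop("counts lacks field '", f, "'", call. = FALSE)
  if (counts$exposed_total <= 0)
    stop("exposed group is empty; indicators undefined", call. = FALSE)
  if (counts$unexposed_total <= 0)
    stop("unexposed group is empty; indicators undefined", call. = FALSE)
  if (population_total <= 0)
    stop("population total must be positive", call. = FALSE)
  stopifnot(counts$exposed_events <= counts$exposed_total,
            counts$unexposed_events <= counts$unexposed_total,
            population_events <= population_total)
  ie <- counts$exposed_events / counts$exposed_total
  iu <- counts$unexposed_events / counts$unexposed_total
  it <- population_events / population_total
  if (iu <= 0 || it <= 0)
    stop("zero incidence in the unexposed group or population; ratio indicators undefined",
         call. = FALSE)
  structure(list(
    incidence_total = it, incidence_exposed = ie, incidence_unexposed = iu,
    rr = ie / iu,
    ar = (ie - iu) * 100,
    par = it - iu,
    par_pct = (it - iu) / it * 100,
    pfp = (ie - it) / ie * 100,
    morbidities_averted = population_total * (ie - it)),
    class = "epi_indicators")
}

#' @export
print.epi_indicators <- function(x, digits = 2, ...) {
  cat(sprintf("Incidence: total %.2f%%, exposed %.2f%%, unexposed %.2f%%\n",
              100 * x$incidence_total, 100 * x$incidence_exposed,
              100 * x$incidence_unexposed))
  cat(sprintf("RR %.2f | AR %.2f | PAR %.2f | PAR%% %.2f | PFP %.2f | averted %.2f\n",
              round_half_up(x$rr, digits), round_half_up(x$ar, digits),
              round_half_up(x$par, digits), round_half_up(x$par_pct, digits),
              round_half_up(x$pfp, digits),
              round_half_up(x$morbidities_averted, digits)))
  invisible(x)
}

#' Indicator table, overall and by GRS risk subgroup
#'
#' One column for the whole cohort and one per GRS group, each holding
#' event counts, incidence and the full indicator panel computed with the
#' stratum's own population totals. Strata with an empty exposed or
#' unexposed group have the ratio-based entries flagged `NA`. The sum of
#' per-stratum morbidities averted is reported alongside the pooled value
#' (the two need not agree exactly).
#'
#' @param scored A scored cohort from [score_cohort()].
#' @return Data frame of class `indicator_table`, one row per indicator,
#'   columns `overall`, `low`, `intermediate`, `high`; the summed
#'   per-stratum averted count is attached as attribute
#'   `averted_stratum_sum`.
#' @export
indicator_table <- function(scored) {
  strata <- c(list(overall = NULL), stats::setNames(as.list(gl_grs_groups()),
                                                    gl_grs_groups()))
  rows <- c("n", "events", "incidence_pct", "rr", "ar", "par", "par_pct",
            "pfp", "morbidities_averted")
  out <- as.data.frame(matrix(NA_real_, nrow = length(rows),
                              ncol = length(strata),
                              dimnames = list(rows, names(strata))))
  for (nm in names(strata)) {
    stratum <- strata[[nm]]
    dat <- if (is.null(stratum)) scored else
      scored[!is.na(scored$grs_group) & scored$grs_group == stratum, , drop = FALSE]
    if (nrow(dat) == 0) next
    out["n", nm] <- nrow(dat)
    out["events", nm] <- sum(dat$hypertension)
    out["incidence_pct", nm] <- 100 * mean(dat$hypertension)
    cnt <- tabulate_exposure(scored, stratum = stratum)
    ind <- tryCatch(compute_indicators(cnt, population_total = nrow(dat),
                                       population_events = sum(dat$hypertension)),
                    error = function(e) NULL)
    if (!is.null(ind))
      out[c("rr", "ar", "par", "par_pct", "pfp", "morbidities_averted"), nm] <-
        unlist(ind[c("rr", "ar", "par", "par_pct", "pfp", "morbidities_averted")])
  }
  structure(out, class = c("indicator_table", "data.frame"),
            averted_stratum_sum = sum(unlist(out["morbidities_averted",
                                                 gl_grs_groups()]), na.rm = TRUE))
}

#' @export
print.indicator_table <- function(x, ...) {
  cat("Epidemiological indicators by genetic risk subgroup\n")
  print.data.frame(round(as.data.frame(x), 2))
  cat(sprintf("Sum of per-stratum morbidities averted: %.2f (pooled: %.2f)\n",
              attr(x, "averted_stratum_sum"), x["morbidities_averted", "overall"]))
  invisible(x)
}
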