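test_that("indicator arithmetic matches the hand-computed oracle", {
  ind <- compute_indicators(list(exposed_events = 20, exposed_total = 100,
                                 unexposed_events = 10, unexposed_total = 100),
                            population_total = 200, population_events = 30)
  expect_equal(ind$rr, 2)
  expect_equal(ind$ar, 10)
  expect_equal(ind$par, 0.05)
  expect_equal(ind$par_pct, (0.15 - 0.10) / 0.15 * 100)
  expect_equal(ind$pfp, (0.20 - 0.15) / 0.20 * 100)  # = 25
  expect_equal(ind$morbidities_averted, 10)
})

test_that("no-effect exposure yields identity indicators", {
  ind <- compute_indicators(list(exposed_events = 30, exposed_total = 150,
                                 unexposed_events = 10, unexposed_total = 50),
                            population_total = 200, population_events = 40)
  expect_equal(ind$rr, 1)
  expect_equal(ind$ar, 0)
  expect_equal(ind$par, 0)
  expect_equal(ind$pfp, 0)
  expect_equal(ind$morbidities_averted, 0)
})

test_that("algebraic identities hold to numerical precision on random panels", {
  set.seed(14)
  for (i in 1:50) {
    et <- sample(50:400, 1); eu <- sample(50:400, 1)
    ee <- sample(1:(et - 1), 1); ue <- sample(1:(eu - 1), 1)
    ind <- compute_indicators(list(exposed_events = ee, exposed_total = et,
                                   unexposed_events = ue, unexposed_total = eu),
                              population_total = et + eu,
                              population_events = ee + ue)
    it <- ind$incidence_total; iu <- ind$incidence_unexposed
    expect_equal(ind$par_pct, ind$par / it * 100, tolerance = 1e-12)
    expect_equal(ind$ar, (ind$rr - 1) * iu * 100, tolerance = 1e-12)
    expect_equal(ind$morbidities_averted,
                 (ee + ue) * ind$pfp / (100 - ind$pfp), tolerance = 1e-9)
  }
})

test_that("RR, AR and PFP increase strictly with exposed incidence", {
  base <- function(ee) compute_indicators(
    list(exposed_events = ee, exposed_total = 1000,
         unexposed_events = 100, unexposed_total = 1000),
    population_total = 2000, population_events = ee + 100)
  prev <- base(150)
  for (ee in c(200, 300, 450)) {
    cur <- base(ee)
    expect_gt(cur$rr, prev$rr)
    expect_gt(cur$ar, prev$ar)
    expect_gt(cur$pfp, prev$pfp)
    prev <- cur
  }
})

test_that("exposure tabulation counts scores 0-3 as exposed, with stratum filtering", {
  sc <- make_scored(lifestyle_score = c(0, 2, 3, 4, 5, 1),
                    hypertension = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                    grs_group = c("low", "low", "high", "high", "low", "high"))
  cnt <- tabulate_exposure(sc)
  expect_equal(cnt$exposed_total, 4)
  expect_equal(cnt$exposed_events, 2)
  expect_equal(cnt$unexposed_total, 2)
  expect_equal(cnt$unexposed_events, 1)
  cnt_low <- tabulate_exposure(sc, stratum = "low")
  expect_equal(cnt_low$exposed_total, 2)   # scores 0, 2
  expect_equal(cnt_low$exposed_events, 2)
  expect_equal(cnt_low$unexposed_total, 1) # score 5
  expect_equal(cnt_low$unexposed_events, 0)
})

test_that("degenerate exposure groups are explicit errors", {
  sc <- make_scored(lifestyle_score = rep(5, 10), hypertension = rep(FALSE, 10))
  cnt <- tabulate_exposure(sc)
  expect_equal(cnt$exposed_total, 0)
  expect_error(compute_indicators(cnt, 10, 0), "exposed group is empty")
  sc2 <- make_scored(lifestyle_score = rep(1, 10), hypertension = rep(TRUE, 10))
  expect_error(compute_indicators(tabulate_exposure(sc2), 10, 10),
               "unexposed group is empty")
})

test_that("indicators equal direct per-subject counting on random small cohorts", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(40:200, 1)
    sc <- make_scored(lifestyle_score = sample(0:5, n, TRUE),
                      hypertension = runif(n) < 0.3)
    if (sum(sc$lifestyle_score <= 3) == 0 || sum(sc$lifestyle_score > 3) == 0) next
    exp_idx <- sc$lifestyle_score <= 3
    ie <- mean(sc$hypertension[exp_idx]); iu <- mean(sc$hypertension[!exp_idx])
    if (iu == 0 || mean(sc$hypertension) == 0) next
    ind <- compute_indicators(tabulate_exposure(sc), n, sum(sc$hypertension))
    expect_equal(ind$rr, ie / iu)
    expect_equal(ind$ar, (ie - iu) * 100)
    expect_equal(ind$par, mean(sc$hypertension) - iu)
    expect_equal(ind$morbidities_averted, n * (ie - mean(sc$hypertension)))
  }
})

test_that("the stratified table is internally consistent with pooled counts", {
  co <- generate_cohort(sim_config(n_subjects = 2500, seed = 19))
  sc <- score_cohort(co)
  tab <- indicator_table(sc)
  expect_equal(colnames(tab), c("overall", "low", "intermediate", "high"))
  pooled <- compute_indicators(tabulate_exposure(sc), nrow(sc), sum(sc$hypertension))
  expect_equal(tab["rr", "overall"], pooled$rr)
  expect_equal(tab["morbidities_averted", "overall"], pooled$morbidities_averted)
  expect_equal(sum(unlist(tab["events", c("low", "intermediate", "high")])),
               tab["events", "overall"])
  expect_type(attr(tab, "averted_stratum_sum"), "double")
})
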