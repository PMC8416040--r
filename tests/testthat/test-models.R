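test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  d <- expand_2x2(10, 20, 30, 40)
  ft <- fit_logistic(d$y, data.frame(x = d$x))
  expect_equal(unname(ft$coefficients["x"]), log((10 * 40) / (20 * 30)),
               tolerance = 1e-7)
  # intercept is the unexposed log-odds
  expect_equal(unname(ft$coefficients["(Intercept)"]), log(30 / 40),
               tolerance = 1e-7)
  # OR and Wald CI on the exponentiated scale bracket the point estimate
  row <- ft$estimates[ft$estimates$term == "x", ]
  expect_true(row$conf.low < row$estimate && row$estimate < row$conf.high)
  # covariance symmetric positive semi-definite
  expect_equal(ft$covariance, t(ft$covariance))
  expect_true(all(eigen(ft$covariance, only.values = TRUE)$values > -1e-12))
})

test_that("logistic fit flags degenerate designs", {
  d <- expand_2x2(10, 20, 30, 40)
  expect_error(fit_logistic(d$y, data.frame(x = d$x, x2 = d$x)),
               "collinear")
  expect_error(fit_logistic(rep(1, 20), data.frame(x = rnorm(20))),
               "single class")
  # complete separation
  y <- c(rep(1, 20), rep(0, 20))
  expect_error(suppressWarnings(fit_logistic(y, data.frame(x = y))), "separation")
})

test_that("linear fit is exact on noise-free data and equals group-mean differences", {
  x <- seq(0, 9)
  ft <- fit_linear(2 + 3 * x, data.frame(x = x))
  expect_equal(unname(ft$coefficients), c(2, 3), tolerance = 1e-10)

  # two-group design: coefficient = difference of hand-computed group means
  g <- rep(c(0, 1), each = 5)
  y <- c(118, 121, 119, 124, 120, 131, 127, 133, 129, 126)
  ft2 <- fit_linear(y, data.frame(g = g))
  expect_equal(unname(ft2$coefficients["g"]),
               mean(y[g == 1]) - mean(y[g == 0]), tolerance = 1e-10)

  expect_error(fit_linear(rnorm(3), data.frame(a = rnorm(3), b = rnorm(3), c = rnorm(3))),
               "n <= p|collinear")
})

test_that("separate associations use the documented references and model tags", {
  cfg <- analysis_config(seed = 5)
  co <- generate_cohort(sim_config(n_subjects = 3000, seed = 5))
  sc <- score_cohort(co, cfg)
  tab <- separate_associations(sc, cfg)
  expect_setequal(unique(tab$model_tag), c("model1", "model2", "model3"))
  expect_setequal(unique(tab$outcome), c("hypertension", "sbp", "dbp"))
  # reference rows: OR 1 for hypertension, beta 0 for BP
  ref_l <- tab[tab$exposure == "lifestyle" & tab$level == "unhealthful", ]
  expect_true(all(ref_l$estimate[ref_l$outcome == "hypertension"] == 1))
  expect_true(all(ref_l$estimate[ref_l$outcome != "hypertension"] == 0))
  ref_g <- tab[tab$exposure == "grs" & tab$level == "low", ]
  expect_true(all(ref_g$estimate[ref_g$outcome == "hypertension"] == 1))
  # every non-reference contrast has a finite CI bracketing its estimate
  nonref <- tab[!(tab$level %in% c("unhealthful", "low")), ]
  expect_true(all(nonref$conf.low <= nonref$estimate &
                    nonref$estimate <= nonref$conf.high))
})

test_that("a missing exposure level is flagged absent, others still fitted", {
  set.seed(8)
  sc <- make_scored(lifestyle_score = sample(0:3, 400, TRUE),
                    hypertension = runif(400) < 0.2)
  cfg <- analysis_config(covariate_set = character(0))
  tab <- separate_associations(sc, cfg)
  h <- tab[tab$exposure == "lifestyle" & tab$outcome == "hypertension" &
             tab$model_tag == "model1", ]
  expect_true(is.na(h$estimate[h$level == "healthful"]))
  expect_false(is.na(h$estimate[h$level == "intermediate"]))
})

test_that("crude joint grid equals hand-computed contingency odds ratios", {
  # 9 cells with hand-countable outcomes, no covariates
  set.seed(21)
  cells <- expand.grid(grs = gl_grs_groups(), ls = gl_lifestyle_groups(),
                       stringsAsFactors = FALSE)
  events <- c(12, 15, 20, 10, 14, 18, 6, 9, 13)
  totals <- rep(60, 9)
  df <- do.call(rbind, lapply(seq_len(9), function(i) {
    data.frame(grs_group = cells$grs[i], lifestyle_group = cells$ls[i],
               hypertension = rep(c(TRUE, FALSE), c(events[i], totals[i] - events[i])))
  }))
  df$grs_group <- factor(df$grs_group, levels = gl_grs_groups())
  df$lifestyle_group <- factor(df$lifestyle_group, levels = gl_lifestyle_groups())
  df$followup_sbp <- rnorm(nrow(df), 120, 5)
  df$followup_dbp <- df$followup_sbp - 40
  df$grs <- runif(nrow(df))
  grid <- joint_effect_grid(df, analysis_config(), adjusted = FALSE)
  # reference cell low:healthful -> events 6 of 60
  ref_odds <- 6 / 54
  for (i in seq_len(9)) {
    cell <- paste(cells$grs[i], cells$ls[i], sep = ":")
    expected <- if (cell == "low:healthful") 1 else
      (events[i] / (60 - events[i])) / ref_odds
    expect_equal(grid$or[grid$cell == cell], expected, tolerance = 1e-6,
                 info = cell)
  }
  expect_equal(grid$n, rep(60L, 9))
  expect_equal(grid$events, as.integer(events))
})

test_that("empty grid cells are flagged sparse and omitted from the model", {
  set.seed(22)
  sc <- make_scored(lifestyle_score = c(rep(0, 40), rep(3, 40), rep(5, 40)),
                    hypertension = runif(120) < 0.3,
                    grs_group = rep(c("low", "high"), 60))
  grid <- joint_effect_grid(sc, analysis_config(covariate_set = character(0)))
  sparse <- grid[grid$grs_group == "intermediate", ]
  expect_true(all(sparse$sparse))
  expect_true(all(is.na(sparse$or)))
  expect_false(any(grid$sparse[grid$grs_group != "intermediate"]))
})
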