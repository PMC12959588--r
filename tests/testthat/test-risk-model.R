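test_that("intercept-only fit equals the logit of the observed proportion", {
  y <- rep(c(1, 0), c(25, 75))
  fit <- fit_logistic(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(unname(fit$coefficients), log(25 / 75), tolerance = 1e-8)
})

test_that("a single binary covariate reproduces the 2x2 closed-form log odds ratio", {
  # x = 0: 20 events / 100; x = 1: 40 events / 100
  x <- rep(c(0, 1), each = 100)
  y <- c(rep(c(1, 0), c(20, 80)), rep(c(1, 0), c(40, 60)))
  fit <- fit_logistic(cbind("(Intercept)" = 1, x = x), y)
  expect_equal(unname(fit$coefficients["x"]), log((40 / 60) / (20 / 80)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(20 / 80),
               tolerance = 1e-6)
})

test_that("the score vanishes at every reported optimum", {
  set.seed(10)
  fits <- list(
    fit_logistic(cbind(1, rnorm(50)), rbinom(50, 1, 0.5)),
    fit_risk_model(complete_case_filter(
      generate_trial(ist3_trial_config(n_patients = 400, seed = 31)))$table)
  )
  for (f in fits) expect_lt(max(abs(f$score)), 1e-6)
})

test_that("degenerate fitting inputs raise classed errors", {
  set.seed(20)
  X <- cbind(1, rnorm(20))
  expect_error(fit_logistic(X, rep(1, 20)), class = "riskhte_degenerate_design_error")
  expect_error(fit_logistic(cbind(1, 1:3, (1:3) * 2), c(0, 1, 1)),
               class = "riskhte_degenerate_design_error")
  # perfect separation: x fully determines y
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(cbind(1, xs), ys), class = "riskhte_separation_error")
})

test_that("design matrix has one indicator per non-reference level", {
  tab <- complete_case_filter(
    generate_trial(ist3_trial_config(n_patients = 300, seed = 12)))$table
  d <- build_design(tab)
  expect_true("sex=Male" %in% d$terms)
  expect_false(any(grepl("sex=Female", d$terms)))
  expect_identical(sum(grepl("^stroke_subtype=", d$terms)), 3L)
  expect_true(all(c("stroke_subtype=PACI", "stroke_subtype=POCI",
                    "stroke_subtype=TACI") %in% d$terms))
  expect_identical(d$terms[1], "(Intercept)")

  # a single observed level is a degenerate design
  df <- as.data.frame(tab)[1:5, ]
  df$sex <- "Female"
  tab5 <- trial_table(df, tt_schema(tab))
  expect_error(build_design(tab5), class = "riskhte_degenerate_design_error")
})

test_that("the risk model is treatment-blinded: permuting treatment changes nothing", {
  tab <- complete_case_filter(
    generate_trial(ist3_trial_config(n_patients = 500, seed = 23)))$table
  fit1 <- fit_risk_model(tab)
  df <- as.data.frame(tab)
  set.seed(1)
  df$treatment <- sample(df$treatment)
  fit2 <- fit_risk_model(trial_table(df, tt_schema(tab)))
  expect_identical(fit1$coefficients, fit2$coefficients)
  expect_identical(fit1$linear_predictor, fit2$linear_predictor)
  expect_identical(fit1$metrics, fit2$metrics)
})

test_that("predicted probabilities are the expit of the linear predictor", {
  tab <- complete_case_filter(
    generate_trial(ist3_trial_config(n_patients = 300, seed = 2)))$table
  fit <- fit_risk_model(tab)
  expect_equal(fit$predicted_probability, plogis(fit$linear_predictor),
               tolerance = 1e-12)
  expect_identical(length(fit$linear_predictor), fit$n_used)
  expect_false("treatment" %in% fit$terms)
})

test_that("c statistic matches exhaustive pair enumeration on random tables", {
  expect_equal(c_statistic(c(.1, .4, .8, .9), c(0, 0, 1, 1)), 1.0)
  expect_equal(c_statistic(rep(.3, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  set.seed(404)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))          # both classes guaranteed
    p <- round(runif(n), sample(1:3, 1))          # coarse rounding forces ties
    expect_equal(c_statistic(p, y), cstat_brute(p, y), tolerance = 1e-12)
  }
  expect_error(c_statistic(c(.2, .3), c(1, 1)),
               class = "riskhte_undefined_metric_error")
})

test_that("Brier score is the mean squared error of the forecast", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(rep(0.5, 7), c(1, 0, 0, 1, 1, 0, 1)), 0.25)
  expect_equal(brier_score(c(0.2, 0.9), c(0, 1)), (0.04 + 0.01) / 2)
  expect_error(brier_score(c(-0.1, 0.5), c(0, 1)), class = "riskhte_argument_error")
})

test_that("calibration recovers slope 1 / intercept 0 on self-generated data", {
  set.seed(88)
  lp <- rnorm(30000, -0.5, 1.3)
  y <- rbinom(length(lp), 1, plogis(lp))
  cal <- calibration(plogis(lp), y)
  expect_lt(abs(cal[["slope"]] - 1), 0.05)
  expect_lt(abs(cal[["intercept"]]), 0.05)
  # halving the logit doubles the recalibration slope
  cal2 <- calibration(plogis(lp / 2), y)
  expect_lt(abs(cal2[["slope"]] - 2), 0.1)
  expect_error(calibration(rep(0.4, 50), rbinom(50, 1, 0.4)),
               class = "riskhte_degenerate_design_error")
})

test_that("odds-ratio table carries Wald CIs on the exponentiated scale", {
  tab <- complete_case_filter(
    generate_trial(ist3_trial_config(n_patients = 600, seed = 77)))$table
  fit <- fit_risk_model(tab)
  ort <- or_table(fit)
  expect_identical(ort$term, fit$terms)
  expect_equal(ort$odds_ratio, exp(ort$estimate), tolerance = 1e-12)
  i <- match("age", ort$term)
  se <- sqrt(fit$covariance["age", "age"])
  expect_equal(ort$ci_low[i], exp(fit$coefficients[["age"]] - 1.959964 * se),
               tolerance = 1e-12)
  expect_true(all(ort$ci_low < ort$odds_ratio & ort$odds_ratio < ort$ci_high))
})
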