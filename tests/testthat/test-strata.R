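test_that("quartile binning partitions evenly spaced probabilities", {
  s <- quantile_bins(seq(0.1, 0.8, by = 0.1), n_bins = 4)
  expect_identical(s$sizes, rep(2L, 4))
  expect_identical(levels(s$assignment), paste0("Q", 1:4))
  expect_identical(sum(s$sizes), 8L)
})

test_that("binning matches hand-computed interpolated quantiles on 9 values", {
  p <- c(0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80)
  # type-7 quantiles of 9 ordered values: h = 1 + p(n-1) -> order stats 3, 5, 7
  s <- quantile_bins(p, n_bins = 4)
  expect_equal(s$edges, c(0.20, 0.40, 0.60))
  # [., .2): {.10, .15}; [.2, .4): {.20, .30}; [.4, .6): {.40, .50}; rest top
  expect_identical(s$sizes, c(2L, 2L, 2L, 3L))
  expect_identical(as.character(s$assignment[p == 0.20]), "Q2")  # tie at the cut goes up
  expect_identical(as.character(s$assignment[p == 0.80]), "Q4")  # top interval closed
})

test_that("single-bin stratification is the identity grouping", {
  p <- runif(17, 0.05, 0.95)
  s <- quantile_bins(p, n_bins = 1)
  expect_identical(s$sizes, 17L)
  expect_identical(length(s$edges), 0L)
})

test_that("degenerate stratification inputs raise classed errors", {
  expect_error(quantile_bins(c(0.2, 0.4), n_bins = 4),
               class = "riskhte_stratification_error")
  expect_error(quantile_bins(c(rep(0.3, 8), 0.5, 0.7), n_bins = 4),
               class = "riskhte_degenerate_strata_error")
  expect_error(quantile_bins(c(0, 0.5, 0.6, 0.7), n_bins = 2),
               class = "riskhte_argument_error")
})

test_that("risk difference, CI and p follow the two-proportion Wald arithmetic", {
  eq <- risk_difference(100, 30, 100, 30)
  expect_equal(eq$risk_difference, 0)
  expect_equal(eq$ci_low, -eq$ci_high)
  expect_equal(eq$p_value, 1)

  e <- risk_difference(100, 30, 100, 40)
  expect_equal(e$risk_difference, -0.10)
  se <- sqrt(0.3 * 0.7 / 100 + 0.4 * 0.6 / 100)
  expect_equal(e$ci_low, -0.10 - 1.959964 * se, tolerance = 1e-12)
  expect_equal(e$ci_high, -0.10 + 1.959964 * se, tolerance = 1e-12)
  pp <- 70 / 200
  z <- -0.10 / sqrt(pp * (1 - pp) * (2 / 100))
  expect_equal(e$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-12)

  expect_error(risk_difference(0, 0, 10, 2), class = "riskhte_undefined_estimate_error")
  expect_error(risk_difference(10, 11, 10, 2), class = "riskhte_argument_error")
})

test_that("the Wald interval agrees with a parametric bootstrap oracle", {
  set.seed(2024)
  B <- 50000
  rd_star <- rbinom(B, 100, 0.30) / 100 - rbinom(B, 100, 0.40) / 100
  boot_ci <- quantile(rd_star, c(0.025, 0.975), type = 7)
  e <- risk_difference(100, 30, 100, 40)
  expect_lt(abs(e$ci_low - boot_ci[[1]]), 0.01)
  expect_lt(abs(e$ci_high - boot_ci[[2]]), 0.01)
})

test_that("CI width shrinks at the root-n rate on fixed proportions", {
  widths <- sapply(c(100, 200, 400, 800), function(n) {
    e <- risk_difference(n, round(0.3 * n), n, round(0.4 * n))
    e$ci_high - e$ci_low
  })
  expect_equal(widths[1:3] / widths[2:4], rep(sqrt(2), 3), tolerance = 1e-12)
})

test_that("stratum effects pool exactly to the overall effect", {
  tab <- generate_trial(small_config(n = 2000, seed = 66, delta = 0.3, gamma = 0.2))
  fit <- fit_risk_model(tab)
  strata <- quantile_bins(fit$predicted_probability, 4)
  eff <- stratified_effects(tab, strata, fit$predicted_probability)
  expect_identical(sum(eff$n_treated + eff$n_control), nrow(tab))  # partition
  pooled <- risk_difference(sum(eff$n_treated), sum(eff$events_treated),
                            sum(eff$n_control), sum(eff$events_control))
  t <- as.integer(as.data.frame(tab)$treatment == "treated")
  y <- as.data.frame(tab)$outcome
  overall <- risk_difference(sum(t), sum(y[t == 1]), sum(1 - t), sum(y[t == 0]))
  expect_identical(pooled$risk_difference, overall$risk_difference)
  expect_identical(pooled$ci_low, overall$ci_low)
})

test_that("identical per-stratum counts reproduce the pooled risk difference", {
  g <- rep(c("A", "B"), each = 40)
  df <- data.frame(
    patient_id = paste0("P", 1:80),
    treatment = rep(rep(c("control", "treated"), each = 20), 2),
    outcome = rep(c(rep(c(1, 0), c(8, 12)), rep(c(1, 0), c(5, 15))), 2),
    age = 70, sex = rep(c("Female", "Male"), 40), nihss = 10,
    stringsAsFactors = FALSE
  )
  tab <- trial_table(df, toy_schema())
  eff <- stratified_effects(tab, g)
  expect_equal(eff$risk_difference[1], eff$risk_difference[2])
  pooled <- risk_difference(40, sum(eff$events_treated), 40, sum(eff$events_control))
  expect_equal(eff$risk_difference[1], pooled$risk_difference)
})

test_that("an empty arm yields a flagged row, not a failure", {
  set.seed(15)
  df <- data.frame(
    patient_id = paste0("P", 1:20),
    treatment = c(rep("control", 10), rep(c("control", "treated"), 5)),
    outcome = rbinom(20, 1, 0.5),
    age = rnorm(20, 70), sex = rep(c("Female", "Male"), 10),
    nihss = rpois(20, 9), stringsAsFactors = FALSE
  )
  df$outcome[1:2] <- c(0, 1)
  tab <- trial_table(df, toy_schema())
  g <- rep(c("empty_arm", "both_arms"), each = 10)
  expect_warning(eff <- stratified_effects(tab, g), "empty arm")
  expect_false(eff$defined[eff$scope == "empty_arm"])
  expect_true(is.na(eff$risk_difference[eff$scope == "empty_arm"]))
  expect_true(eff$defined[eff$scope == "both_arms"])
})

test_that("estimated stratum benefits track the generative truth", {
  cfg <- small_config(n = 20000, seed = 314, delta = 0.2, gamma = 0.5)
  tab <- generate_trial(cfg)
  fit <- fit_risk_model(tab)
  strata <- quantile_bins(fit$predicted_probability, 4)
  eff <- stratified_effects(tab, strata, fit$predicted_probability)
  truth <- tapply(attr(tab, "true_rd"), strata$assignment, mean)
  expect_true(all(eff$ci_low <= truth & truth <= eff$ci_high))
  # heterogeneity direction: benefit grows with baseline risk when gamma > 0
  expect_gt(eff$risk_difference[4], eff$risk_difference[1])
})

test_that("subgroup splits label every patient deterministically", {
  tab <- toy_table(n = 12, seed = 7)
  g_age <- subgroup_split(tab, "age", threshold = 75)
  expect_identical(levels(g_age), c("age<75", "age>=75"))
  expect_identical(as.character(g_age), ifelse(tab$age < 75, "age<75", "age>=75"))
  g_sex <- subgroup_split(tab, "sex")
  expect_identical(levels(g_sex), c("sex=Female", "sex=Male"))
  expect_error(subgroup_split(tab, "age"), class = "riskhte_argument_error")
  expect_error(subgroup_split(tab, "bogus"), class = "riskhte_argument_error")
})

test_that("overlap coefficients behave at the extremes and match the Normal oracle", {
  set.seed(99)
  x <- runif(400, 0.2, 0.8)
  same <- subgroup_distributions(c(x, x), rep(c("a", "b"), each = 400))
  expect_equal(same$overlap["a", "b"], 1, tolerance = 1e-9)
  expect_equal(same$overlap["a", "a"], 1, tolerance = 1e-9)

  disjoint <- subgroup_distributions(c(runif(400, 0.05, 0.2), runif(400, 0.7, 0.95)),
                                     rep(c("lo", "hi"), each = 400))
  expect_lt(disjoint$overlap["lo", "hi"], 0.02)

  # closed-form overlap of two equal-sd Normals: 2 * pnorm(-|dm| / (2 s))
  m1 <- 0.35; m2 <- 0.45; s <- 0.05
  g1 <- rnorm(10000, m1, s); g2 <- rnorm(10000, m2, s)
  ov <- subgroup_distributions(c(g1, g2), rep(c("g1", "g2"), each = 10000))
  expect_lt(abs(ov$overlap["g1", "g2"] - 2 * pnorm(-abs(m1 - m2) / (2 * s))), 0.02)
})

test_that("tiny groups keep summaries but omit densities", {
  d <- subgroup_distributions(c(0.4, 0.2, 0.3, 0.5), c("solo", "trio", "trio", "trio"))
  expect_identical(d$summary$n[d$summary$group == "solo"], 1L)
  expect_true(all(is.na(d$densities[, "solo"])))
  expect_false(anyNA(d$densities[, "trio"]))
  expect_true(is.na(d$overlap["solo", "trio"]))
})
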