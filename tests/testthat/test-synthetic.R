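test_that("same configuration and seed reproduce an identical table", {
  cfg <- small_config(n = 300, seed = 42)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "true_lp"), attr(t2, "true_lp"))
  # and the caller's RNG state is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_trial(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("configuration invariants are enforced", {
  covs <- list(covariate_spec("x1", "continuous"))
  expect_error(synthetic_trial_config(0, covs), class = "riskhte_config_error")
  expect_error(synthetic_trial_config(10, covs, allocation_ratio = 1),
               class = "riskhte_config_error")
  expect_error(synthetic_trial_config(10, covs, coefficients = c(bogus = 1)),
               class = "riskhte_config_error")
  # coefficient named after a reference level is unknown too
  expect_error(
    synthetic_trial_config(10, list(
      covariate_spec("grp", "binary", levels = c("A", "B"), probs = c(.5, .5))),
      coefficients = c("grp=A" = 1)),
    class = "riskhte_config_error")
  expect_error(covariate_spec("p", "binary", levels = c("A", "B"), probs = c(.5, .6)),
               class = "riskhte_config_error")
})

test_that("null configuration gives equal outcome proportions across arms", {
  cfg <- small_config(n = 20000, seed = 11, delta = 0, gamma = 0)
  tab <- generate_trial(cfg)
  y <- as.data.frame(tab)$outcome
  trt <- as.data.frame(tab)$treatment
  diff <- abs(mean(y[trt == "treated"]) - mean(y[trt == "control"]))
  expect_lt(diff, 0.025)  # ~3.5 binomial SDs at n/arm = 10000
})

test_that("with zero coefficients the prevalence converges to expit(intercept)", {
  cfg <- synthetic_trial_config(
    n_patients = 100000,
    covariates = list(covariate_spec("x1", "continuous")),
    coefficients = NULL, intercept = qlogis(0.357), seed = 5
  )
  tab <- generate_trial(cfg)
  prev <- mean(as.data.frame(tab)$outcome)
  # 99% binomial CI half-width at n = 1e5 is 0.0039
  expect_lt(abs(prev - 0.357), 0.005)
})

test_that("a unit log-odds covariate effect is recovered empirically", {
  cfg <- synthetic_trial_config(
    n_patients = 200000,
    covariates = list(covariate_spec("grp", "binary",
                                     levels = c("A", "B"), probs = c(.5, .5))),
    coefficients = c("grp=B" = 1.0), intercept = -0.5, seed = 17
  )
  df <- as.data.frame(generate_trial(cfg))
  odds <- function(p) p / (1 - p)
  lodiff <- log(odds(mean(df$outcome[df$grp == "B"]))) -
    log(odds(mean(df$outcome[df$grp == "A"])))
  expect_lt(abs(lodiff - 1.0), 0.05)
})

test_that("treatment effect acts through main effect and centered-LP interaction", {
  # strong positive main effect must raise the treated arm's outcome rate
  cfg <- small_config(n = 20000, seed = 3, delta = 1.0, gamma = 0)
  df <- as.data.frame(generate_trial(cfg))
  expect_gt(mean(df$outcome[df$treatment == "treated"]),
            mean(df$outcome[df$treatment == "control"]) + 0.1)
  # generative truth attributes are consistent: gamma = 0 means a common
  # log-odds shift, so true_rd = expit(lp + delta) - expit(lp)
  tab <- generate_trial(cfg)
  lp <- attr(tab, "true_lp")
  expect_equal(attr(tab, "true_rd"), plogis(lp + 1.0) - plogis(lp))
})

test_that("missingness injection is MCAR on covariate cells only", {
  cfg <- small_config(n = 200, seed = 8)
  tab <- generate_trial(cfg)
  expect_identical(inject_missingness(tab, 0, seed = 1), tab)
  m1 <- inject_missingness(tab, 0.5, seed = 21)
  m2 <- inject_missingness(tab, 0.5, seed = 21)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_false(anyNA(m1$patient_id))
  expect_false(anyNA(m1$treatment))
  expect_error(inject_missingness(tab, 1), class = "riskhte_argument_error")
  expect_error(inject_missingness(tab, -0.1), class = "riskhte_argument_error")
})

test_that("realized missing-cell count matches its binomial expectation", {
  # 10 rows x 5 covariate columns at rate 0.99: expectation 49.5, sd 0.70
  cfg <- synthetic_trial_config(
    n_patients = 10,
    covariates = lapply(paste0("x", 1:5), covariate_spec, kind = "continuous"),
    seed = 2
  )
  tab <- inject_missingness(generate_trial(cfg), 0.99, seed = 4)
  n_missing <- sum(is.na(as.data.frame(tab)[paste0("x", 1:5)]))
  expect_gte(n_missing, 46)
  expect_lte(n_missing, 50)
})

test_that("synthetic configs round-trip through YAML", {
  cfg <- ist3_trial_config(n_patients = 50, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_config(cfg, path)
  cfg2 <- read_trial_config(path)
  expect_equal(cfg2$coefficients, cfg$coefficients, tolerance = 1e-14)
  expect_equal(cfg2$intercept, cfg$intercept, tolerance = 1e-14)
  expect_identical(plain_df(generate_trial(cfg2)),
                   plain_df(generate_trial(cfg)))
})
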