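# Shared fixtures and independent oracles, built in code at test time.

toy_schema <- function() {
  variable_schema(list(
    schema_variable("treatment", "binary", c("control", "treated"), role = "treatment"),
    schema_variable("outcome", "binary", c("0", "1"), role = "outcome"),
    schema_variable("age", "continuous"),
    schema_variable("sex", "binary", c("Female", "Male")),
    schema_variable("nihss", "continuous")
  ))
}

toy_table <- function(n = 10, seed = 1) {
  set.seed(seed)
  trial_table(data.frame(
    patient_id = paste0("P", seq_len(n)),
    treatment = rep(c("control", "treated"), length.out = n),
    outcome = rbinom(n, 1, 0.4),
    age = round(rnorm(n, 75, 8), 1),
    sex = sample(c("Female", "Male"), n, replace = TRUE),
    nihss = rpois(n, 10),
    stringsAsFactors = FALSE
  ), toy_schema())
}

# Two-covariate generator config for fast simulation tests.
small_config <- function(n = 500, seed = 1, delta = 0, gamma = 0,
                         intercept = -0.3) {
  synthetic_trial_config(
    n_patients = n,
    covariates = list(
      covariate_spec("x1", "continuous", mean = 0, sd = 1),
      covariate_spec("grp", "binary", levels = c("A", "B"), probs = c(0.5, 0.5))
    ),
    coefficients = c("x1" = 0.8, "grp=B" = -0.5),
    intercept = intercept,
    treatment_main_effect = delta,
    interaction_strength = gamma,
    seed = seed
  )
}

# Exhaustive pair-count concordance oracle (quadratic; independent of the
# rank-based implementation).
cstat_brute <- function(predicted, outcome) {
  pos <- predicted[outcome == 1]
  neg <- predicted[outcome == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Drop generative bookkeeping attributes so tables can be compared on content.
plain_df <- function(tab) {
  df <- as.data.frame(tab)
  attr(df, "true_lp") <- NULL
  attr(df, "true_rd") <- NULL
  attr(df, "schema") <- NULL
  df
}

# Strip the one volatile report field so determinism can be asserted.
drop_timestamp <- function(report) {
  report$provenance$timestamp <- NULL
  report
}
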