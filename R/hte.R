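#' Likelihood-ratio test for risk-based treatment-effect heterogeneity
#'
#' Step two of the risk-modeling HTE workflow. Two nested logistic models
#' are fit to the same complete-case rows, with the risk model's linear
#' predictor (LP) treated as a fixed, known covariate:
#'
#' * null: `outcome ~ treatment + LP`
#' * alternative: `outcome ~ treatment + LP + treatment:LP`
#'
#' The statistic is the deviance drop between them, referred to a 1-df
#' chi-square distribution. The full continuous linear predictor is used —
#' the test does not depend on any downstream binning choice — and the
#' statistic is invariant to affine rescaling of the LP. Because the LP is
#' estimated on the same patients, no estimation uncertainty is propagated
#' from step one; this in-sample reuse follows the usual (apparent,
#' potentially optimistic) practice and is documented in the methods
#' vignette.
#'
#' @param table A [trial_table()], complete on outcome and predictors;
#'   rows must be those the risk model was fit on.
#' @param fit A [fit_risk_model()] result aligned to `table` (same rows,
#'   same order).
#' @return An `interaction_test` with fields `deviance_null`,
#'   `deviance_alt`, `lr_statistic`, `df` (1), `p_value`,
#'   `interaction_coefficient`, `interaction_se`, `n`.
#' @export
lr_interaction_test <- function(table, fit) {
  if (!inherits(fit, "risk_model_fit")) {
    abort("`fit` must be a risk_model_fit.", "riskhte_argument_error")
  }
  if (fit$n_used != nrow(table)) {
    abort(sprintf("fit used %d rows but table has %d; align them (complete-case filter first).",
                  fit$n_used, nrow(table)), "riskhte_argument_error")
  }
  trt <- treatment_indicator(table)
  y <- outcome_vector(table)
  lp <- fit$linear_predictor
  if (length(unique(trt)) < 2L) {
    abort("constant treatment: interaction test is degenerate.",
          "riskhte_degenerate_design_error")
  }
  if (stats::sd(lp) == 0) {
    abort("constant linear predictor: interaction test is degenerate.",
          "riskhte_degenerate_design_error")
  }
  X0 <- cbind("(Intercept)" = 1, treatment = trt, lp = lp)
  X1 <- cbind(X0, "treatment:lp" = trt * lp)
  fit0 <- fit_logistic(X0, y)
  fit1 <- fit_logistic(X1, y)
  lr <- fit0$deviance - fit1$deviance
  if (lr < -1e-8) {
    abort(sprintf("nested deviances out of order (LR = %.3g); numerical failure.", lr),
          "riskhte_numerical_error")
  }
  lr <- max(lr, 0)
  structure(list(deviance_null = fit0$deviance,
                 deviance_alt = fit1$deviance,
                 lr_statistic = lr,
                 df = 1L,
                 p_value = stats::pchisq(lr, df = 1L, lower.tail = FALSE),
                 interaction_coefficient = unname(fit1$coefficients[["treatment:lp"]]),
                 interaction_se = sqrt(fit1$vcov["treatment:lp", "treatment:lp"]),
                 treatment_coefficient = unname(fit1$coefficients[["treatment"]]),
                 alt_coefficients = fit1$coefficients,
                 n = length(y)),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat("<interaction_test> likelihood-ratio test, treatment x linear predictor\n")
  cat(sprintf("  LR = %.4f on %d df, p = %.4f\n", x$lr_statistic, x$df, x$p_value))
  cat(sprintf("  interaction coefficient %.4f (SE %.4f), n = %d\n",
              x$interaction_coefficient, x$interaction_se, x$n))
  invisible(x)
}
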