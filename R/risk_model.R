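#' Build the risk-model design matrix
#'
#' Intercept, one column per continuous predictor (entered linearly and
#' untransformed), and one indicator column per non-reference level of each
#' binary/categorical predictor. Column names are deterministic: the
#' variable name for continuous predictors, `"name=Level"` for indicators.
#' The allocated treatment is never part of the design — the risk model is
#' treatment-blinded by construction.
#'
#' @param table A [trial_table()], complete on all predictors.
#' @param schema A [variable_schema()]; defaults to the table's schema.
#' @return A list with `X` (numeric matrix, n x p) and `terms` (column
#'   names).
#' @export
build_design <- function(table, schema = tt_schema(table)) {
  preds <- schema_predictors(schema)
  if (!length(preds)) {
    abort("schema declares no predictors.", "riskhte_schema_error")
  }
  sub <- as.data.frame(table)[, preds, drop = FALSE]
  if (anyNA(sub)) {
    abort("predictors contain missing values; run complete_case_filter() first.",
          "riskhte_validation_error")
  }
  cols <- list("(Intercept)" = rep(1, nrow(sub)))
  for (v in preds) {
    spec <- schema[[v]]
    if (spec$kind == "continuous") {
      cols[[v]] <- as.numeric(sub[[v]])
    } else {
      x <- factor(sub[[v]], levels = spec$levels)
      observed <- unique(as.character(x))
      if (length(observed) < 2L) {
        abort(sprintf("predictor '%s' has a single observed level ('%s'): degenerate design.",
                      v, observed), "riskhte_degenerate_design_error")
      }
      ref <- spec$reference
      for (lev in setdiff(spec$levels, ref)) {
        cols[[paste0(v, "=", lev)]] <- as.numeric(x == lev)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, terms = names(cols))
}

#' Maximum-likelihood logistic regression on a prepared design matrix
#'
#' Bernoulli-logit fit by iteratively reweighted least squares (via the
#' standard [stats::glm.fit()] engine, convergence tolerance `1e-10`, at
#' most 100 iterations). The coefficient covariance is the inverse of the
#' observed information at the optimum. Coefficients whose magnitude
#' exceeds 15 on the log-odds scale are treated as evidence of (quasi-)
#' complete separation and raise an error rather than being reported.
#'
#' @param X Numeric design matrix, including any intercept column.
#' @param y Binary 0/1 outcome vector, both classes present.
#' @return A `logistic_fit` list: `coefficients`, `vcov`, `deviance`
#'   (-2 log-likelihood), `linear_predictor`, `fitted`, `score` (the
#'   log-likelihood gradient at the optimum), `converged`, `n`.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    abort("design and outcome lengths differ.", "riskhte_argument_error")
  }
  if (anyNA(X) || anyNA(y)) {
    abort("design/outcome contain missing values.", "riskhte_validation_error")
  }
  if (!all(y %in% c(0, 1))) {
    abort("outcome must be binary 0/1.", "riskhte_validation_error")
  }
  if (length(unique(y)) < 2L) {
    abort("outcome has a single class; the logistic likelihood is degenerate.",
          "riskhte_degenerate_design_error")
  }
  if (nrow(X) <= ncol(X)) {
    abort(sprintf("need more observations (%d) than model terms (%d).",
                  nrow(X), ncol(X)), "riskhte_degenerate_design_error")
  }
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient (collinear or constant columns).",
          "riskhte_degenerate_design_error")
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100L))
  )
  if (!fit$converged) {
    cond <- errorCondition(
      "logistic fit did not converge within 100 iterations.",
      class = c("riskhte_nonconvergence_error", "riskhte_error"))
    cond$last_coefficients <- fit$coefficients
    stop(cond)
  }
  beta <- fit$coefficients
  if (any(abs(beta) > 15)) {
    abort(sprintf("separation suspected: coefficient(s) %s exceed 15 in magnitude.",
                  paste(names(beta)[abs(beta) > 15], collapse = ", ")),
          "riskhte_separation_error")
  }
  p <- fit$fitted.values
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta,
                 vcov = vcov,
                 deviance = fit$deviance,
                 linear_predictor = as.numeric(X %*% beta),
                 fitted = as.numeric(p),
                 score = as.numeric(crossprod(X, y - p)),
                 converged = TRUE,
                 n = nrow(X)),
            class = "logistic_fit")
}

#' Fit the treatment-blinded multivariable risk model
#'
#' Step one of the risk-modeling HTE workflow: a multivariable logistic
#' regression for the favorable outcome using the baseline predictors only
#' — never the allocated treatment — so predicted probabilities describe
#' baseline risk, not treatment response. Performance is summarized by the
#' c statistic (concordance / area under the ROC curve), the Brier score,
#' and the logistic calibration intercept and slope.
#'
#' @param table A [trial_table()], complete on outcome and predictors (run
#'   [complete_case_filter()] first).
#' @param schema Optional [variable_schema()] override.
#' @return A `risk_model_fit` with fields `terms`, `coefficients`,
#'   `covariance`, `linear_predictor`, `predicted_probability`,
#'   `converged`, `n_used`, `metrics` (c statistic, Brier score,
#'   calibration intercept/slope) and `or_table` (per-term odds ratios
#'   with Wald 95% CIs and p-values).
#' @export
fit_risk_model <- function(table, schema = tt_schema(table)) {
  y <- as.integer(table[[schema_outcome(schema)]])
  if (anyNA(y)) {
    abort("outcome contains missing values; run complete_case_filter() first.",
          "riskhte_validation_error")
  }
  design <- build_design(table, schema)
  check_conditioning(design$X)
  fit <- fit_logistic(design$X, y)
  p <- fit$fitted
  cal <- calibration(p, y)
  metrics <- list(c_statistic = c_statistic(p, y),
                  brier_score = brier_score(p, y),
                  calibration_intercept = cal[["intercept"]],
                  calibration_slope = cal[["slope"]])
  structure(list(terms = design$terms,
                 coefficients = fit$coefficients,
                 covariance = fit$vcov,
                 linear_predictor = fit$linear_predictor,
                 predicted_probability = p,
                 deviance = fit$deviance,
                 score = fit$score,
                 converged = fit$converged,
                 n_used = fit$n,
                 metrics = metrics,
                 or_table = or_table_from(fit$coefficients, fit$vcov)),
            class = "risk_model_fit")
}

# Scale-invariant collinearity diagnostic on the predictor cross-product.
check_conditioning <- function(X) {
  xtx <- crossprod(X)
  r <- tryCatch(stats::cov2cor(xtx), warning = function(w) NULL)
  if (is.null(r)) return(invisible())
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    warning("design matrix is near-collinear (condition diagnostic); coefficient estimates may be unstable.",
            call. = FALSE)
  }
  invisible()
}

or_table_from <- function(beta, vcov, z = 1.959964) {
  se <- sqrt(diag(vcov))
  data.frame(term = names(beta),
             estimate = unname(beta),
             se = unname(se),
             odds_ratio = exp(unname(beta)),
             ci_low = exp(unname(beta - z * se)),
             ci_high = exp(unname(beta + z * se)),
             p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname fit_risk_model
#' @param fit A `risk_model_fit`.
#' @export
or_table <- function(fit) {
  fit$or_table
}

#' @export
print.risk_model_fit <- function(x, ...) {
  cat(sprintf("<risk_model_fit> treatment-blinded logistic model, n = %d, %d terms\n",
              x$n_used, length(x$terms)))
  cat(sprintf("  c statistic %.3f | Brier score %.3f | calibration slope %.3f\n",
              x$metrics$c_statistic, x$metrics$brier_score,
              x$metrics$calibration_slope))
  tab <- x$or_table
  tab[-1] <- lapply(tab[-1], function(z) round(z, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Concordance (c) statistic
#'
#' The proportion of (favorable, unfavorable) patient pairs in which the
#' favorable-outcome patient has the higher predicted probability, ties
#' counted one half; identical to the area under the ROC curve. Computed
#' with midranks in O(n log n).
#'
#' @param predicted Predicted probabilities (any monotone score works).
#' @param outcome Binary 0/1 outcomes, both classes present.
#' @return A value in `[0, 1]`.
#' @export
c_statistic <- function(predicted, outcome) {
  check_prediction_pair(predicted, outcome, probability_scale = FALSE)
  outcome <- as.numeric(outcome)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    abort("c statistic undefined: only one outcome class present.",
          "riskhte_undefined_metric_error")
  }
  r <- rank(predicted)  # midranks handle ties as half-concordances
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; 0 is perfect, 0.25 is an uninformative constant 0.5.
#'
#' @inheritParams c_statistic
#' @return A value in `[0, 1]`.
#' @export
brier_score <- function(predicted, outcome) {
  check_prediction_pair(predicted, outcome, probability_scale = TRUE)
  mean((as.numeric(predicted) - as.numeric(outcome))^2)
}

#' Logistic calibration intercept and slope
#'
#' Regresses the outcome on the model's linear predictor (logit of the
#' predicted probability): the slope is the coefficient of the linear
#' predictor (1 for a perfectly calibrated model), and the intercept is
#' the calibration-in-the-large term from a refit with the linear
#' predictor as a fixed offset (0 for a perfectly calibrated model).
#'
#' @inheritParams c_statistic
#' @return Named numeric vector `c(intercept, slope)`.
#' @export
calibration <- function(predicted, outcome) {
  check_prediction_pair(predicted, outcome, probability_scale = TRUE)
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2L) {
    abort("calibration undefined: only one outcome class present.",
          "riskhte_undefined_metric_error")
  }
  lp <- stats::qlogis(pmin(pmax(as.numeric(predicted), 1e-12), 1 - 1e-12))
  if (stats::sd(lp) == 0) {
    abort("constant linear predictor: calibration slope is degenerate.",
          "riskhte_degenerate_design_error")
  }
  slope_fit <- fit_logistic(cbind("(Intercept)" = 1, lp = lp), y)
  off <- suppressWarnings(
    stats::glm.fit(matrix(1, length(y), 1), y, family = stats::binomial(),
                   offset = lp,
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100L))
  )
  c(intercept = unname(off$coefficients[1L]),
    slope = unname(slope_fit$coefficients[["lp"]]))
}

check_prediction_pair <- function(predicted, outcome, probability_scale) {
  if (length(predicted) != length(outcome) || !length(predicted)) {
    abort("`predicted` and `outcome` must be non-empty and equal length.",
          "riskhte_argument_error")
  }
  if (anyNA(predicted) || anyNA(outcome)) {
    abort("missing values in predictions or outcomes.", "riskhte_validation_error")
  }
  if (!all(outcome %in% c(0, 1))) {
    abort("outcome must be binary 0/1.", "riskhte_validation_error")
  }
  if (probability_scale && (any(predicted < 0) || any(predicted > 1))) {
    abort("predictions must lie in [0, 1].", "riskhte_argument_error")
  }
}
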