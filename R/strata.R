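#' Quantile-based risk strata
#'
#' Step three of the risk-modeling HTE workflow: patients are binned by
#' the empirical quantiles of their predicted probability of a favorable
#' outcome (quartiles by default, Q1 = lowest predicted probability).
#' Interior cut points use the linear-interpolation quantile definition
#' (`type = 7`, the default of mainstream statistical environments).
#' A patient falls in the lowest stratum whose half-open interval
#' `[edge_low, edge_high)` contains its probability; the top interval is
#' closed, and ties at a cut point go to the higher stratum (i.e. the
#' lower stratum keeps values strictly below the cut), deterministically.
#'
#' @param probabilities Predicted probabilities in (0, 1).
#' @param n_bins Number of strata (default 4, i.e. quartiles Q1-Q4).
#' @return A `risk_strata` with fields `n_bins`, `edges` (the interior
#'   `k/n_bins` quantiles), `assignment` (factor Q1..Qk, one per patient),
#'   `sizes`, and `mean_probability` per stratum.
#' @export
quantile_bins <- function(probabilities, n_bins = 4L) {
  p <- as.numeric(probabilities)
  if (!is_scalar_number(n_bins) || n_bins < 1 || n_bins != round(n_bins)) {
    abort("`n_bins` must be a positive integer.", "riskhte_argument_error")
  }
  if (anyNA(p)) {
    abort("probabilities contain missing values.", "riskhte_validation_error")
  }
  if (any(p <= 0) || any(p >= 1)) {
    abort("probabilities must lie strictly inside (0, 1).", "riskhte_argument_error")
  }
  if (length(p) < n_bins) {
    abort(sprintf("cannot form %d strata from %d observations.", n_bins, length(p)),
          "riskhte_stratification_error")
  }
  tied <- max(table(p)) / length(p)
  if (tied > 0.5) {
    abort(sprintf("degenerate strata: %.0f%% of probabilities share one value; quantile cut points collapse.",
                  100 * tied), "riskhte_degenerate_strata_error")
  }
  n_bins <- as.integer(n_bins)
  edges <- if (n_bins > 1L) {
    unname(stats::quantile(p, probs = seq_len(n_bins - 1L) / n_bins, type = 7))
  } else {
    numeric(0)
  }
  if (length(edges) && any(diff(edges) <= 0)) {
    abort("degenerate strata: quantile cut points are not strictly increasing.",
          "riskhte_degenerate_strata_error")
  }
  labels <- paste0("Q", seq_len(n_bins))
  idx <- findInterval(p, edges) + 1L  # [low, high) bins, top interval closed
  assignment <- factor(labels[idx], levels = labels)
  structure(list(n_bins = n_bins,
                 edges = edges,
                 assignment = assignment,
                 sizes = as.integer(table(assignment)),
                 mean_probability = as.numeric(tapply(p, assignment, mean))),
            class = "risk_strata")
}

#' @export
print.risk_strata <- function(x, ...) {
  cat(sprintf("<risk_strata> %d quantile strata of predicted probability\n", x$n_bins))
  cat(sprintf("  cut points: %s\n",
              if (length(x$edges)) paste(round(x$edges, 4), collapse = ", ") else "none"))
  cat(sprintf("  sizes: %s\n", paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Absolute risk difference between trial arms
#'
#' Step four's effect scale: the difference in favorable-outcome
#' proportions, treated minus control. The 95% confidence interval is the
#' Wald interval with unpooled variances, `RD +/- 1.959964 *
#' sqrt(p_t(1-p_t)/n_t + p_c(1-p_c)/n_c)` (no continuity correction), and
#' the two-sided p-value comes from the pooled-variance two-proportion z
#' statistic.
#'
#' @param n_treated,n_control Arm sizes (> 0).
#' @param events_treated,events_control Favorable-outcome counts.
#' @param scope Label carried into reports (`"overall"`, a stratum label,
#'   or a subgroup label).
#' @return An `effect_estimate`: one-row data.frame with `scope`,
#'   `n_treated`, `events_treated`, `n_control`, `events_control`,
#'   `risk_treated`, `risk_control`, `risk_difference`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
risk_difference <- function(n_treated, events_treated, n_control, events_control,
                            scope = "overall") {
  counts <- c(n_treated, events_treated, n_control, events_control)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers.", "riskhte_argument_error")
  }
  if (n_treated == 0 || n_control == 0) {
    abort("zero patients in an arm: risk difference undefined.",
          "riskhte_undefined_estimate_error")
  }
  if (events_treated > n_treated || events_control > n_control) {
    abort("event counts cannot exceed arm sizes.", "riskhte_argument_error")
  }
  z <- 1.959964
  pt <- events_treated / n_treated
  pc <- events_control / n_control
  rd <- pt - pc
  se <- sqrt(pt * (1 - pt) / n_treated + pc * (1 - pc) / n_control)
  # pooled-variance z test of pt == pc
  pp <- (events_treated + events_control) / (n_treated + n_control)
  se0 <- sqrt(pp * (1 - pp) * (1 / n_treated + 1 / n_control))
  p_value <- if (se0 == 0) 1 else 2 * stats::pnorm(-abs(rd / se0))
  structure(data.frame(scope = scope,
                       n_treated = n_treated, events_treated = events_treated,
                       n_control = n_control, events_control = events_control,
                       risk_treated = pt, risk_control = pc,
                       risk_difference = rd,
                       ci_low = rd - z * se, ci_high = rd + z * se,
                       p_value = p_value,
                       stringsAsFactors = FALSE),
            class = c("effect_estimate", "data.frame"))
}

#' Treatment benefit per risk stratum or subgroup
#'
#' Computes one empirical (count-based) absolute risk difference per group
#' via [risk_difference()], plus the group's mean predicted probability
#' (the x-coordinate of a benefit-versus-baseline-risk display). A group
#' with an empty arm yields a flagged row with missing estimates rather
#' than a pipeline failure.
#'
#' @param table A [trial_table()] with complete treatment and outcome.
#' @param groups A [quantile_bins()] result, or a factor/character vector
#'   with one group label per patient.
#' @param probabilities Optional predicted probabilities (taken from the
#'   strata assignment input when `groups` is a `risk_strata`); used for
#'   the per-group mean.
#' @return A data.frame with one row per group: the [risk_difference()]
#'   columns plus `mean_probability` and `defined`.
#' @export
stratified_effects <- function(table, groups, probabilities = NULL) {
  if (inherits(groups, "risk_strata")) {
    g <- groups$assignment
  } else {
    g <- factor(groups)
  }
  if (length(g) != nrow(table)) {
    abort("group labels and table rows differ in length.", "riskhte_argument_error")
  }
  if (anyNA(g)) {
    abort("every patient needs a group label.", "riskhte_validation_error")
  }
  trt <- treatment_indicator(table)
  y <- outcome_vector(table)
  if (anyNA(y)) {
    abort("outcome contains missing values; run complete_case_filter() first.",
          "riskhte_validation_error")
  }
  rows <- lapply(levels(g), function(lev) {
    sel <- g == lev
    nt <- sum(sel & trt == 1L); et <- sum(sel & trt == 1L & y == 1L)
    nc <- sum(sel & trt == 0L); ec <- sum(sel & trt == 0L & y == 1L)
    mp <- if (!is.null(probabilities)) mean(probabilities[sel]) else NA_real_
    if (nt == 0 || nc == 0) {
      warning(sprintf("group '%s' has an empty arm; estimate undefined.", lev),
              call. = FALSE)
      out <- data.frame(scope = lev, n_treated = nt, events_treated = et,
                        n_control = nc, events_control = ec,
                        risk_treated = NA_real_, risk_control = NA_real_,
                        risk_difference = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
      out$mean_probability <- mp
      out$defined <- FALSE
      return(out)
    }
    out <- as.data.frame(risk_difference(nt, et, nc, ec, scope = lev))
    out$mean_probability <- mp
    out$defined <- TRUE
    out
  })
  do.call(rbind, rows)
}

#' Split patients into a traditional one-variable subgroup
#'
#' Categorical variables split by level; continuous variables split at a
#' threshold (labels `"var<thr"` and `"var>=thr"`). The default age split
#' used by the pipeline is 80 years — a convention near the emulated
#' cohort's median age, configurable and flagged as such in reports.
#'
#' @param table A [trial_table()].
#' @param variable Predictor name.
#' @param threshold Threshold for a continuous variable (required there,
#'   ignored for categorical ones).
#' @return A factor with one subgroup label per patient.
#' @export
subgroup_split <- function(table, variable, threshold = NULL) {
  s <- tt_schema(table)
  if (!variable %in% schema_names(s)) {
    abort(sprintf("unknown variable '%s'.", variable), "riskhte_argument_error")
  }
  x <- table[[variable]]
  if (anyNA(x)) {
    abort(sprintf("variable '%s' has missing values; filter first.", variable),
          "riskhte_validation_error")
  }
  if (s[[variable]]$kind == "continuous") {
    if (!is_scalar_number(threshold)) {
      abort(sprintf("continuous variable '%s' needs a `threshold`.", variable),
            "riskhte_argument_error")
    }
    labs <- c(sprintf("%s<%g", variable, threshold),
              sprintf("%s>=%g", variable, threshold))
    factor(ifelse(x < threshold, labs[1L], labs[2L]), levels = labs)
  } else {
    factor(paste0(variable, "=", as.character(x)),
           levels = paste0(variable, "=", s[[variable]]$levels))
  }
}

#' Predicted-probability distributions by group
#'
#' Summarizes how predicted baseline probabilities distribute within risk
#' strata or traditional subgroups: per-group n, mean, median and
#' quartiles, plus a Gaussian-kernel density evaluated on a fixed grid
#' over `[0, 1]` (groups with fewer than 2 members keep their summary but
#' omit the density). Pairwise overlap coefficients — the integral of the
#' pointwise minimum of two group densities, 1 for identical
#' distributions, near 0 for disjoint ones — quantify how well a grouping
#' separates baseline risk.
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param grouping Factor/character vector, one label per patient, or a
#'   [quantile_bins()] result.
#' @param grid_n Number of grid points on `[0, 1]` (default 512).
#' @return A `subgroup_distributions` list: `summary` (data.frame),
#'   `grid`, `densities` (matrix grid x group, `NA` column when omitted),
#'   `overlap` (symmetric matrix of overlap coefficients).
#' @export
subgroup_distributions <- function(probabilities, grouping, grid_n = 512L) {
  p <- as.numeric(probabilities)
  g <- if (inherits(grouping, "risk_strata")) grouping$assignment else factor(grouping)
  if (length(p) != length(g) || anyNA(p) || anyNA(g)) {
    abort("probabilities and grouping must be complete and equal length.",
          "riskhte_validation_error")
  }
  grid <- seq(0, 1, length.out = grid_n)
  levs <- levels(g)
  summary <- do.call(rbind, lapply(levs, function(lev) {
    x <- p[g == lev]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7)
    data.frame(group = lev, n = length(x), mean = mean(x),
               q25 = unname(q[1L]), median = unname(q[2L]), q75 = unname(q[3L]),
               stringsAsFactors = FALSE)
  }))
  densities <- sapply(levs, function(lev) {
    x <- p[g == lev]
    if (length(x) < 2L || stats::sd(x) == 0) return(rep(NA_real_, grid_n))
    d <- stats::density(x, from = 0, to = 1, n = grid_n)$y
    d / trapezoid(grid, d)  # renormalize mass clipped at the boundaries
  })
  k <- length(levs)
  overlap <- matrix(NA_real_, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (!anyNA(densities[, i]) && !anyNA(densities[, j])) {
        overlap[i, j] <- trapezoid(grid, pmin(densities[, i], densities[, j]))
      }
    }
  }
  structure(list(summary = summary, grid = grid, densities = densities,
                 overlap = overlap),
            class = "subgroup_distributions")
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.subgroup_distributions <- function(x, ...) {
  cat(sprintf("<subgroup_distributions> %d groups on a %d-point grid\n",
              nrow(x$summary), length(x$grid)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Model-based risk-difference curve
#'
#' Companion to the empirical stratum estimates: evaluates the interaction
#' model's implied absolute risk difference as a function of the linear
#' predictor, for plotting the treatment-benefit curve over baseline risk.
#'
#' @param test An [lr_interaction_test()] result.
#' @param fit The [fit_risk_model()] result supplying the LP distribution.
#' @param lp_grid Linear-predictor values at which to evaluate the curve;
#'   defaults to an even grid across the observed LP range.
#' @return A data.frame with `lp`, `baseline_probability`,
#'   `risk_difference`.
#' @export
model_rd_curve <- function(test, fit, lp_grid = NULL) {
  if (!inherits(test, "interaction_test") || is.null(test$alt_coefficients)) {
    abort("`test` must be an lr_interaction_test() result.", "riskhte_argument_error")
  }
  if (is.null(lp_grid)) {
    r <- range(fit$linear_predictor)
    lp_grid <- seq(r[1L], r[2L], length.out = 101L)
  }
  b <- test$alt_coefficients
  p_control <- expit(b[["(Intercept)"]] + b[["lp"]] * lp_grid)
  p_treated <- expit(b[["(Intercept)"]] + b[["treatment"]] +
                       (b[["lp"]] + b[["treatment:lp"]]) * lp_grid)
  data.frame(lp = lp_grid,
             baseline_probability = p_control,
             risk_difference = p_treated - p_control)
}
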