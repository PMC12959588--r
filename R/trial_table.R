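#' Construct a validated patient-level trial table
#'
#' A `trial_table` is a `data.frame` (one row per randomized patient) with
#' an attached [variable_schema()]. Construction coerces columns to their
#' declared kinds and enforces the invariants the downstream analysis
#' relies on: unique patient identifiers, a never-missing treatment column
#' restricted to its declared levels, an outcome coded 0/1 (missing
#' allowed), and categorical values drawn from the declared levels.
#'
#' @param data A data.frame containing `patient_id` plus every schema
#'   variable.
#' @param schema A [variable_schema()].
#' @param validate Set to `FALSE` to skip checks when the caller has just
#'   produced a valid table (internal fast path).
#' @return A `trial_table` (data.frame subclass with a `schema` attribute).
#' @export
trial_table <- function(data, schema, validate = TRUE) {
  if (!inherits(schema, "variable_schema")) {
    abort("`schema` must be a variable_schema.", "riskhte_schema_error")
  }
  if (!is.data.frame(data)) {
    abort("`data` must be a data.frame.", "riskhte_argument_error")
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  needed <- c("patient_id", schema_names(schema))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
          "riskhte_schema_error")
  }
  out_var <- schema_outcome(schema)
  trt_var <- schema_treatment(schema)
  for (v in schema) {
    col <- data[[v$name]]
    if (v$name == out_var) {
      col <- suppressWarnings(as.integer(as.character(col)))
      bad <- which(!is.na(col) & !col %in% c(0L, 1L))
      if (validate && length(bad)) {
        abort(sprintf("outcome '%s' must be 0/1; offending row(s): %s",
                      v$name, paste(utils::head(bad, 5L), collapse = ", ")),
              "riskhte_validation_error")
      }
      data[[v$name]] <- col
    } else if (v$kind == "continuous") {
      data[[v$name]] <- as.numeric(col)
    } else {
      chr <- as.character(col)
      bad <- which(!is.na(chr) & !chr %in% v$levels)
      if (validate && length(bad)) {
        abort(sprintf("variable '%s': value(s) outside declared levels at row(s) %s: %s",
                      v$name,
                      paste(utils::head(bad, 5L), collapse = ", "),
                      paste(utils::head(unique(chr[bad]), 5L), collapse = ", ")),
              "riskhte_validation_error")
      }
      data[[v$name]] <- factor(chr, levels = v$levels)
    }
  }
  if (validate) {
    if (anyDuplicated(data$patient_id)) {
      abort("patient_id values must be unique.", "riskhte_validation_error")
    }
    if (anyNA(data[[trt_var]])) {
      abort("treatment must never be missing.", "riskhte_validation_error")
    }
  }
  data <- data[, needed, drop = FALSE]
  rownames(data) <- NULL
  attr(data, "schema") <- schema
  class(data) <- c("trial_table", "data.frame")
  data
}

#' @rdname trial_table
#' @param table A `trial_table`.
#' @export
tt_schema <- function(table) {
  s <- attr(table, "schema")
  if (is.null(s)) {
    abort("object carries no variable schema; build it with trial_table().",
          "riskhte_argument_error")
  }
  s
}

#' @export
print.trial_table <- function(x, ...) {
  s <- attr(x, "schema")
  cat(sprintf("<trial_table> %d patients, %d predictors\n",
              nrow(x), length(schema_predictors(s))))
  n_missing <- sum(is.na(x[, schema_names(s), drop = FALSE]))
  cat(sprintf("  treatment: %s | outcome: %s | missing cells: %d\n",
              schema_treatment(s), schema_outcome(s), n_missing))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# 0/1 treatment indicator in table row order.
treatment_indicator <- function(table) {
  s <- tt_schema(table)
  trt <- table[[schema_treatment(s)]]
  lev <- s[[schema_treatment(s)]]$levels
  as.integer(trt == lev[[2L]])
}

outcome_vector <- function(table) {
  as.integer(table[[schema_outcome(tt_schema(table))]])
}
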