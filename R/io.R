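#' Write a trial table to CSV
#'
#' UTF-8, header row, one row per patient, empty cell for a missing value;
#' columns ordered `patient_id`, treatment, outcome, then predictors in
#' schema order.
#'
#' @param table A [trial_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(table, path) {
  s <- tt_schema(table)
  cols <- c("patient_id", schema_treatment(s), schema_outcome(s), schema_predictors(s))
  df <- as.data.frame(table)[, cols, drop = FALSE]
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

MISSING_TOKENS <- c("", "na", "nan")

#' Read and validate a patient-level trial CSV
#'
#' Cells equal (case-insensitively) to the empty string, `"NA"` or `"NaN"`
#' are read as missing. Continuous cells that fail to parse as numbers are
#' set missing with a warning naming the column and rows. Categorical
#' values outside the declared levels raise a validation error naming the
#' offending rows and values.
#'
#' @param path CSV path. The header must contain `patient_id` and every
#'   schema variable; extra columns are ignored.
#' @param schema A [variable_schema()].
#' @return A [trial_table()].
#' @export
read_trial_csv <- function(path, schema) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), "riskhte_input_error")
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                              "riskhte_input_error")
  )
  if (nrow(df) == 0L) {
    abort(sprintf("input file '%s' contains no data rows.", path), "riskhte_input_error")
  }
  needed <- c("patient_id", schema_names(schema))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(sprintf("missing required column(s) in '%s': %s", path,
                  paste(missing_cols, collapse = ", ")), "riskhte_schema_error")
  }
  df <- df[, needed, drop = FALSE]
  for (v in schema) {
    col <- df[[v$name]]
    col[tolower(trimws(col)) %in% MISSING_TOKENS] <- NA
    if (v$kind == "continuous" && v$name != schema_outcome(schema)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        warning(sprintf("column '%s': %d unparseable cell(s) set missing (rows %s)",
                        v$name, length(bad),
                        paste(utils::head(bad, 5L), collapse = ", ")),
                call. = FALSE)
      }
      df[[v$name]] <- num
    } else {
      df[[v$name]] <- col
    }
  }
  trial_table(df, schema)
}

#' Complete-case filter
#'
#' Retains exactly the rows with no missing value among `variables`
#' (default: treatment, outcome, and every predictor in the schema), in
#' their original order, and reports what was dropped and why.
#'
#' @param table A [trial_table()].
#' @param variables Variables whose completeness is required; must be a
#'   subset of the schema names.
#' @return A list with elements `table` (the filtered `trial_table`) and
#'   `report`, a `complete_case_report` with fields `n_input`,
#'   `n_retained`, `n_dropped` and `dropped_by_variable` (for each
#'   filtering variable with any missing value, the number of input rows
#'   missing it).
#' @export
complete_case_filter <- function(table, variables = NULL) {
  s <- tt_schema(table)
  if (is.null(variables)) {
    variables <- c(schema_treatment(s), schema_outcome(s), schema_predictors(s))
  }
  unknown <- setdiff(variables, schema_names(s))
  if (length(unknown)) {
    abort(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")),
          "riskhte_argument_error")
  }
  sub <- as.data.frame(table)[, variables, drop = FALSE]
  miss <- is.na(sub)
  keep <- rowSums(miss) == 0L
  by_var <- colSums(miss)
  by_var <- by_var[by_var > 0L]
  by_var <- as.list(stats::setNames(as.integer(by_var), names(by_var)))
  filtered <- table[keep, , drop = FALSE]
  attr(filtered, "schema") <- s
  class(filtered) <- c("trial_table", "data.frame")
  rownames(filtered) <- NULL
  # generative attributes (if present) must stay aligned to the rows
  for (a in c("true_lp", "true_rd")) {
    if (!is.null(attr(table, a))) attr(filtered, a) <- attr(table, a)[keep]
  }
  report <- structure(list(n_input = nrow(table),
                           n_retained = as.integer(sum(keep)),
                           n_dropped = as.integer(sum(!keep)),
                           dropped_by_variable = by_var,
                           variables = variables),
                      class = "complete_case_report")
  list(table = filtered, report = report)
}

#' @export
print.complete_case_report <- function(x, ...) {
  cat(sprintf("<complete_case_report> %d of %d rows retained (%d dropped)\n",
              x$n_retained, x$n_input, x$n_dropped))
  if (length(x$dropped_by_variable)) {
    for (v in names(x$dropped_by_variable)) {
      cat(sprintf("  missing %-22s %d row(s)\n", v, x$dropped_by_variable[[v]]))
    }
  }
  invisible(x)
}

#' Field-name mapping for externally deposited trial tables
#'
#' Raw exports of deposited trial datasets rarely use the analysis-ready
#' column names and level codes this package's schema declares. A mapping
#' file (YAML) translates them: `columns` maps raw column name to schema
#' name, and `values` optionally recodes levels per schema variable. The
#' packaged template `inst/extdata/ist3_field_mapping.yaml` is a
#' user-editable starting point for the deposited IST-3 table; the raw
#' field names it contains must be checked against the dataset's data
#' dictionary before use.
#'
#' @param path YAML mapping file.
#' @return A list with elements `columns` and `values`.
#' @export
read_field_mapping <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("mapping file not found: %s", path), "riskhte_input_error")
  }
  m <- yaml::read_yaml(path)
  if (is.null(m$columns)) {
    abort("mapping file must contain a `columns` map.", "riskhte_input_error")
  }
  list(columns = m$columns, values = m$values %||% list())
}

#' @rdname read_field_mapping
#' @param data A raw data.frame as read from the deposited export.
#' @param mapping A mapping list from `read_field_mapping()`.
#' @return `apply_field_mapping()` returns the data.frame with columns
#'   renamed and values recoded, ready for [trial_table()].
#' @export
apply_field_mapping <- function(data, mapping) {
  cols <- mapping$columns
  missing_cols <- setdiff(unlist(names(cols)), names(data))
  if (length(missing_cols)) {
    abort(sprintf("raw column(s) absent from data: %s",
                  paste(missing_cols, collapse = ", ")), "riskhte_input_error")
  }
  out <- data[, names(cols), drop = FALSE]
  names(out) <- unlist(cols)
  for (v in names(mapping$values)) {
    if (!v %in% names(out)) next
    rec <- mapping$values[[v]]
    x <- as.character(out[[v]])
    mapped <- unlist(rec)[x]
    out[[v]] <- ifelse(is.na(mapped) & !is.na(x), x, mapped)
  }
  out
}
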