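#' Declare a trial variable
#'
#' A variable schema entry describes one column of a patient-level trial
#' table: its name, measurement kind, allowed levels (for binary and
#' categorical variables), the reference level used when building indicator
#' columns, and its role in the analysis.
#'
#' @param name Column name (character scalar).
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`. Binary
#'   variables are categorical variables with exactly two levels.
#' @param levels Allowed category levels, in display order. Required for
#'   binary and categorical variables; ignored for continuous ones.
#' @param reference Reference level; defaults to the first element of
#'   `levels`. The design matrix carries one indicator per non-reference
#'   level.
#' @param role One of `"predictor"`, `"treatment"`, `"outcome"`,
#'   `"ignored"`.
#' @return A `schema_variable` list.
#' @export
schema_variable <- function(name,
                            kind = c("continuous", "binary", "categorical"),
                            levels = NULL, reference = NULL,
                            role = c("predictor", "treatment", "outcome", "ignored")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty character scalar.", "riskhte_schema_error")
  }
  if (kind %in% c("binary", "categorical")) {
    if (is.null(levels) || length(levels) < 2L) {
      abort(sprintf("variable '%s': %s variables need at least two levels.", name, kind),
            "riskhte_schema_error")
    }
    if (kind == "binary" && length(levels) != 2L) {
      abort(sprintf("variable '%s': binary variables need exactly two levels.", name),
            "riskhte_schema_error")
    }
    if (anyDuplicated(levels)) {
      abort(sprintf("variable '%s': duplicated levels.", name), "riskhte_schema_error")
    }
    reference <- reference %||% levels[[1L]]
    if (!reference %in% levels) {
      abort(sprintf("variable '%s': reference level '%s' is not among the declared levels.",
                    name, reference), "riskhte_schema_error")
    }
  } else {
    levels <- NULL
    reference <- NULL
  }
  structure(list(name = name, kind = kind, levels = levels,
                 reference = reference, role = role),
            class = "schema_variable")
}

#' Assemble a variable schema
#'
#' @param variables List of [schema_variable()] entries. Exactly one must
#'   have role `"treatment"` and exactly one role `"outcome"`.
#' @return A `variable_schema` object (named list of variables).
#' @export
variable_schema <- function(variables) {
  if (inherits(variables, "schema_variable")) variables <- list(variables)
  ok <- vapply(variables, inherits, logical(1), what = "schema_variable")
  if (!all(ok)) {
    abort("all schema entries must be built with schema_variable().",
          "riskhte_schema_error")
  }
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicated variable names: %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")),
          "riskhte_schema_error")
  }
  roles <- vapply(variables, `[[`, character(1), "role")
  if (sum(roles == "treatment") != 1L) {
    abort("schema must declare exactly one treatment variable.", "riskhte_schema_error")
  }
  if (sum(roles == "outcome") != 1L) {
    abort("schema must declare exactly one outcome variable.", "riskhte_schema_error")
  }
  trt <- variables[[which(roles == "treatment")]]
  if (trt$kind == "continuous") {
    abort("the treatment variable must be binary.", "riskhte_schema_error")
  }
  names(variables) <- nms
  structure(variables, class = "variable_schema")
}

#' @rdname variable_schema
#' @export
schema_names <- function(schema) {
  vapply(schema, `[[`, character(1), "name")
}

schema_roles <- function(schema) {
  vapply(schema, `[[`, character(1), "role")
}

#' @rdname variable_schema
#' @param schema A `variable_schema`.
#' @export
schema_predictors <- function(schema) {
  unname(schema_names(schema)[schema_roles(schema) == "predictor"])
}

#' @rdname variable_schema
#' @export
schema_treatment <- function(schema) {
  unname(schema_names(schema)[schema_roles(schema) == "treatment"])
}

#' @rdname variable_schema
#' @export
schema_outcome <- function(schema) {
  unname(schema_names(schema)[schema_roles(schema) == "outcome"])
}

#' @export
print.variable_schema <- function(x, ...) {
  cat(sprintf("<variable_schema> %d variables\n", length(x)))
  for (v in x) {
    lv <- if (is.null(v$levels)) "" else {
      sprintf(" [%s; ref=%s]", paste(v$levels, collapse = "/"), v$reference)
    }
    cat(sprintf("  %-22s %-11s %-9s%s\n", v$name, v$kind, v$role, lv))
  }
  invisible(x)
}

#' Default schema for an IST-3-like stroke trial table
#'
#' Declares the treatment arm, the binary 6-month favorable outcome (alive
#' and independent, Oxford Handicap Score 0-2), and the 15 baseline
#' predictors used by the risk model: age, sex, living alone before the
#' stroke, whether a recent ischemic change is the likely cause, recent
#' antiplatelet use, atrial fibrillation at randomization, systolic and
#' diastolic blood pressure, estimated weight, the three Glasgow Coma
#' Scale (GCS) components, total GCS, total NIH Stroke Scale (NIHSS)
#' score, and the Oxfordshire stroke subtype.
#'
#' Reference levels are the first level listed for each variable, matching
#' the order the trial's baseline table reports them in.
#'
#' @return A `variable_schema`.
#' @export
ist3_schema <- function() {
  variable_schema(list(
    schema_variable("treatment", "binary", c("control", "treated"), role = "treatment"),
    schema_variable("outcome", "binary", c("0", "1"), role = "outcome"),
    schema_variable("age", "continuous"),
    schema_variable("sex", "binary", c("Female", "Male")),
    schema_variable("lived_alone", "binary", c("Yes", "No")),
    schema_variable("ischemic_change", "categorical",
                    c("No", "PossiblyYes", "DefinitelyYes")),
    schema_variable("antiplatelet", "binary", c("Yes", "No")),
    schema_variable("atrial_fibrillation", "binary", c("Yes", "No")),
    schema_variable("sbp", "continuous"),
    schema_variable("dbp", "continuous"),
    schema_variable("weight", "continuous"),
    schema_variable("gcs_eye", "binary", c("Nonspontaneous", "Spontaneous")),
    schema_variable("gcs_motor", "binary", c("Normal", "NotNormal")),
    schema_variable("gcs_verbal", "categorical",
                    c("None", "Noises", "InappropriateWords", "Confused", "Orientated")),
    schema_variable("gcs_total", "continuous"),
    schema_variable("nihss", "continuous"),
    schema_variable("stroke_subtype", "categorical", c("LACI", "PACI", "POCI", "TACI"))
  ))
}

#' Read or write a variable schema as YAML
#'
#' The on-disk form is a list of maps with fields `name`, `kind`, `levels`,
#' `reference`, `role`, so schemas can be edited without touching code.
#'
#' @param path File path.
#' @return `read_schema_yaml()` returns a `variable_schema`;
#'   `write_schema_yaml()` returns `path` invisibly.
#' @export
read_schema_yaml <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("schema file not found: %s", path), "riskhte_input_error")
  }
  raw <- yaml::read_yaml(path)
  vars <- lapply(raw, function(v) {
    schema_variable(v$name, v$kind,
                    levels = if (!is.null(v$levels)) as.character(v$levels),
                    reference = v$reference, role = v$role %||% "predictor")
  })
  variable_schema(vars)
}

#' @rdname read_schema_yaml
#' @param schema A `variable_schema`.
#' @export
write_schema_yaml <- function(schema, path) {
  raw <- lapply(unname(schema), function(v) {
    out <- list(name = v$name, kind = v$kind, role = v$role)
    if (!is.null(v$levels)) {
      out$levels <- as.list(v$levels)
      out$reference <- v$reference
    }
    out
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}
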