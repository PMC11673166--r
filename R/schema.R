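#' Declare a table column
#'
#' A column specification records everything the statistics machinery needs to
#' know about one variable of a patient-level table: its kind, its admissible
#' range, an optional clinical risk threshold (the "risky" fraction of a
#' column is the fraction of values strictly beyond this threshold in the
#' stated direction), and whether the column is the binary outcome.
#'
#' @param name Column name (non-empty string, unique within a schema).
#' @param kind One of `"continuous"`, `"count"`, `"binary"`. Count columns are
#'   rounded to integers when tables are synthesized.
#' @param min_value,max_value Admissible range; `min_value <= max_value`.
#' @param risky_threshold Optional threshold defining the risky region;
#'   must lie in `[min_value, max_value]` when given.
#' @param risky_direction `"above"` (risky means value > threshold) or
#'   `"below"` (value < threshold). Required when `risky_threshold` is given.
#' @param is_outcome Is this the binary outcome column? Exactly one column per
#'   schema must be the outcome and its kind must be `"binary"`.
#' @return An object of class `"column_spec"`.
#' @seealso [table_schema()], [pima_schema()]
#' @export
column_spec <- function(name, kind = c("continuous", "count", "binary"),
                        min_value, max_value,
                        risky_threshold = NULL,
                        risky_direction = NULL,
                        is_outcome = FALSE) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  min_value <- as.numeric(min_value)
  max_value <- as.numeric(max_value)
  if (!is.finite(min_value) || !is.finite(max_value))
    stop("column '", name, "': min/max must be finite", call. = FALSE)
  if (min_value > max_value)
    stop("column '", name, "': min_value > max_value", call. = FALSE)
  if (!is.null(risky_threshold)) {
    risky_threshold <- as.numeric(risky_threshold)
    if (risky_threshold < min_value || risky_threshold > max_value)
      stop("column '", name, "': risky_threshold outside [min_value, max_value]",
           call. = FALSE)
    if (is.null(risky_direction))
      stop("column '", name, "': risky_direction required with risky_threshold",
           call. = FALSE)
    risky_direction <- match.arg(risky_direction, c("above", "below"))
  } else {
    risky_direction <- NULL
  }
  if (isTRUE(is_outcome) && kind != "binary")
    stop("column '", name, "': outcome column must be binary", call. = FALSE)
  structure(
    list(name = name, kind = kind,
         min_value = min_value, max_value = max_value,
         risky_threshold = risky_threshold,
         risky_direction = risky_direction,
         is_outcome = isTRUE(is_outcome)),
    class = "column_spec"
  )
}

#' Assemble a table schema
#'
#' A schema is an ordered list of [column_spec()]s plus a default row count.
#' It fixes the serialization order of the statistics vector and is carried
#' by every table, statistics vector and fitted model in the package.
#'
#' @param columns List of `column_spec` objects.
#' @param n_rows_default Default number of patient rows for tables generated
#'   against this schema.
#' @return An object of class `"table_schema"`.
#' @export
table_schema <- function(columns, n_rows_default = 766L) {
  if (!is.list(columns) || length(columns) == 0L ||
      !all(vapply(columns, inherits, logical(1), "column_spec")))
    stop("'columns' must be a non-empty list of column_spec objects", call. = FALSE)
  nm <- vapply(columns, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate column names: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  n_out <- sum(vapply(columns, `[[`, logical(1), "is_outcome"))
  if (n_out != 1L)
    stop("schema must have exactly one outcome column (found ", n_out, ")",
         call. = FALSE)
  n_rows_default <- as.integer(n_rows_default)
  if (is.na(n_rows_default) || n_rows_default < 2L)
    stop("'n_rows_default' must be an integer >= 2", call. = FALSE)
  names(columns) <- nm
  structure(list(columns = columns, n_rows_default = n_rows_default),
            class = "table_schema")
}

#' @export
print.table_schema <- function(x, ...) {
  cat("Table schema:", length(x$columns), "columns,",
      x$n_rows_default, "default rows\n")
  for (cs in x$columns) {
    risky <- if (!is.null(cs$risky_threshold))
      sprintf(", risky %s %g", if (cs$risky_direction == "above") ">" else "<",
              cs$risky_threshold) else ""
    cat(sprintf("  %-28s %-10s [%g, %g]%s%s\n", cs$name, cs$kind,
                cs$min_value, cs$max_value, risky,
                if (cs$is_outcome) "  <outcome>" else ""))
  }
  invisible(x)
}

#' Column names of a schema
#' @param schema A `table_schema`.
#' @return Character vector of column names in schema order.
#' @export
schema_columns <- function(schema) {
  stopifnot(inherits(schema, "table_schema"))
  names(schema$columns)
}

#' Name of the outcome column
#' @param schema A `table_schema`.
#' @return The outcome column's name.
#' @export
outcome_column <- function(schema) {
  stopifnot(inherits(schema, "table_schema"))
  nm <- vapply(schema$columns, `[[`, logical(1), "is_outcome")
  names(schema$columns)[nm]
}

#' Default diabetes-style table schema
#'
#' A nine-column schema emulating a small diabetes cohort table: eight
#' clinical features (pregnancies, glucose, blood pressure, skin thickness,
#' insulin, BMI, diabetes pedigree function, age) plus a binary outcome, with
#' 766 patient rows by default. Ranges and risk thresholds are clinically
#' plausible fixture parameters (e.g. glucose > 140 mg/dL, BMI > 30 kg/m2),
#' not estimates from any particular cohort.
#'
#' @param n_rows_default Default row count (766).
#' @return A `table_schema` with 9 columns.
#' @export
pima_schema <- function(n_rows_default = 766L) {
  table_schema(list(
    column_spec("Pregnancies", "count", 0, 17,
                risky_threshold = 6, risky_direction = "above"),
    column_spec("Glucose", "continuous", 40, 200,
                risky_threshold = 140, risky_direction = "above"),
    column_spec("BloodPressure", "continuous", 40, 122,
                risky_threshold = 90, risky_direction = "above"),
    column_spec("SkinThickness", "continuous", 5, 99,
                risky_threshold = 40, risky_direction = "above"),
    column_spec("Insulin", "continuous", 10, 846,
                risky_threshold = 200, risky_direction = "above"),
    column_spec("BMI", "continuous", 15, 67,
                risky_threshold = 30, risky_direction = "above"),
    column_spec("DiabetesPedigreeFunction", "continuous", 0.05, 2.5,
                risky_threshold = 1, risky_direction = "above"),
    column_spec("Age", "continuous", 21, 81,
                risky_threshold = 50, risky_direction = "above"),
    column_spec("Outcome", "binary", 0, 1, is_outcome = TRUE)
  ), n_rows_default = n_rows_default)
}

#' Read / write a schema as YAML
#'
#' The on-disk format is one YAML mapping per column (kind, min, max, optional
#' risky threshold/direction, is_outcome flag) plus `n_rows_default`.
#'
#' @param path File path.
#' @return `read_schema()` returns a `table_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  cols <- lapply(y$columns, function(cc) {
    column_spec(cc$name, cc$kind, cc$min, cc$max,
                risky_threshold = cc$risky_threshold,
                risky_direction = cc$risky_direction,
                is_outcome = isTRUE(cc$is_outcome))
  })
  table_schema(cols, n_rows_default = y$n_rows_default %||% 766L)
}

#' @rdname read_schema
#' @param schema A `table_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "table_schema"))
  y <- list(
    n_rows_default = schema$n_rows_default,
    columns = lapply(unname(schema$columns), function(cs) {
      out <- list(name = cs$name, kind = cs$kind,
                  min = cs$min_value, max = cs$max_value)
      if (!is.null(cs$risky_threshold)) {
        out$risky_threshold <- cs$risky_threshold
        out$risky_direction <- cs$risky_direction
      }
      if (cs$is_outcome) out$is_outcome <- TRUE
      out
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
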