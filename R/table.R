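#' Patient-level table bound to a schema
#'
#' A `synth_table` is a numeric matrix (rows = patients, columns in schema
#' order) carrying its [table_schema()] as an attribute. Construction
#' validates conformity: column count and names, finite cells, a binary
#' outcome column containing both classes.
#'
#' @param values Numeric matrix or data frame, columns in schema order (or
#'   named so they can be reordered).
#' @param schema A `table_schema`.
#' @param check_range Also require every cell to lie within its column's
#'   `[min_value, max_value]` (default `TRUE`; synthesis and generation
#'   guarantee this, raw external data may not).
#' @return An object of class `"synth_table"` (a numeric matrix).
#' @export
new_table <- function(values, schema, check_range = TRUE) {
  stopifnot(inherits(schema, "table_schema"))
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix or data frame", call. = FALSE)
  cols <- schema_columns(schema)
  if (ncol(values) != length(cols))
    stop("table has ", ncol(values), " columns, schema expects ", length(cols),
         call. = FALSE)
  if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), cols))
      stop("table column names do not match schema", call. = FALSE)
    values <- values[, cols, drop = FALSE]
  } else {
    colnames(values) <- cols
  }
  if (any(!is.finite(values)))
    stop("table contains non-finite cells", call. = FALSE)
  oc <- outcome_column(schema)
  yv <- values[, oc]
  if (!all(yv %in% c(0, 1)))
    stop("outcome column '", oc, "' must be binary 0/1", call. = FALSE)
  if (length(unique(yv)) < 2L)
    stop("outcome column '", oc, "' must contain both classes", call. = FALSE)
  if (check_range) {
    for (cs in schema$columns) {
      v <- values[, cs$name]
      if (any(v < cs$min_value - 1e-9) || any(v > cs$max_value + 1e-9))
        stop("column '", cs$name, "' has cells outside [",
             cs$min_value, ", ", cs$max_value, "]", call. = FALSE)
    }
  }
  structure(values, schema = schema, class = c("synth_table", class(values)))
}

#' @export
print.synth_table <- function(x, ...) {
  cat("synth_table:", nrow(x), "patients x", ncol(x), "columns\n")
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat("... (", nrow(x) - 5L, " more rows)\n", sep = "")
  invisible(x)
}

table_schema_of <- function(table) {
  s <- attr(table, "schema")
  if (is.null(s)) stop("table carries no schema", call. = FALSE)
  s
}

#' Read / write a table as CSV
#'
#' One patient per row, header row of column names, full double precision.
#'
#' @param path File path.
#' @param schema Schema the table must conform to.
#' @return `read_table_csv()` returns a `synth_table`; `write_table_csv()`
#'   returns `path` invisibly.
#' @export
read_table_csv <- function(path, schema) {
  df <- utils::read.csv(path, check.names = FALSE)
  new_table(df, schema)
}

#' @rdname read_table_csv
#' @param table A `synth_table`.
#' @export
write_table_csv <- function(table, path) {
  m <- unclass(table)
  attr(m, "schema") <- NULL
  df <- as.data.frame(m)
  # %.15g keeps doubles lossless enough for re-extraction checks
  df[] <- lapply(df, function(v) formatC(v, format = "g", digits = 15))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
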