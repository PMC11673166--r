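#' The statistic menu of a schema
#'
#' Enumerates, in canonical order, the (column, statistic) pairs that make up
#' a statistics vector for the given schema: `min`, `max`, `mean` for every
#' column; `risky_fraction` and `odds_ratio` for every non-outcome column
#' with a risky threshold; `prevalence` for the outcome column. The order is
#' a pure function of the schema, which makes the flat vector serialization
#' deterministic.
#'
#' @param schema A [table_schema()].
#' @return Data frame with columns `column` and `statistic`.
#' @export
stat_menu <- function(schema) {
  stopifnot(inherits(schema, "table_schema"))
  rows <- lapply(schema$columns, function(cs) {
    st <- c("min", "max", "mean")
    if (cs$is_outcome) st <- c(st, "prevalence")
    else if (!is.null(cs$risky_threshold)) st <- c(st, "risky_fraction", "odds_ratio")
    data.frame(column = cs$name, statistic = st, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stat_names <- function(schema) {
  m <- stat_menu(schema)
  paste0(m$column, "__", m$statistic)
}

new_stats_vector <- function(values, schema) {
  nm <- stat_names(schema)
  stopifnot(length(values) == length(nm))
  structure(stats::setNames(as.numeric(values), nm),
            schema = schema, class = "stats_vector")
}

#' @export
print.stats_vector <- function(x, ...) {
  cat("stats_vector (", length(x), " statistics)\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Fraction of values beyond a risk threshold
#'
#' The "risky" fraction of a column is the share of entries strictly beyond a
#' clinical threshold in the stated direction (e.g. glucose strictly above
#' 140 mg/dL).
#'
#' @param values Non-empty finite numeric vector.
#' @param threshold Threshold value.
#' @param direction `"above"` (risky iff value > threshold) or `"below"`.
#' @return A fraction in `[0, 1]`.
#' @export
risky_fraction <- function(values, threshold, direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("'values' must be finite", call. = FALSE)
  flags <- if (direction == "above") values > threshold else values < threshold
  mean(flags)
}

#' Odds ratio of a binary risk indicator against a binary outcome
#'
#' Cross-product ratio \eqn{(a d)/(b c)} of the 2x2 table with
#' a = risky & case, b = risky & control, c = non-risky & case,
#' d = non-risky & control. When any cell is zero the Haldane-Anscombe
#' continuity correction adds 0.5 to every cell, keeping the odds ratio
#' finite and usable as a conditioning statistic.
#'
#' @param risky_flags,outcome_flags Equal-length binary (0/1 or logical)
#'   vectors.
#' @return Non-negative odds ratio.
#' @export
compute_odds_ratio <- function(risky_flags, outcome_flags) {
  if (length(risky_flags) != length(outcome_flags))
    stop("flag vectors must have equal length", call. = FALSE)
  r <- as.logical(risky_flags)
  y <- as.logical(outcome_flags)
  if (anyNA(r) || anyNA(y)) stop("flags must be binary", call. = FALSE)
  a <- sum(r & y); b <- sum(r & !y); c_ <- sum(!r & y); d <- sum(!r & !y)
  if (min(a, b, c_, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c_)
}

#' Extract the statistics vector of a table
#'
#' Computes, per the schema's [stat_menu()], the per-column min, max and mean,
#' the risky fraction and odds ratio (against the outcome) for feature columns
#' with a risk threshold, and the outcome prevalence. Deterministic and
#' invariant under row permutation.
#'
#' @param table A [new_table()] object (or matrix conforming to `schema`).
#' @param schema The table's schema.
#' @return A `stats_vector`: named numeric vector (names `<column>__<statistic>`)
#'   in canonical menu order, carrying the schema as an attribute.
#' @export
extract_statistics <- function(table, schema = attr(table, "schema")) {
  if (!inherits(table, "synth_table")) table <- new_table(table, schema)
  stopifnot(inherits(schema, "table_schema"))
  if (any(!is.finite(table))) stop("table contains non-finite cells", call. = FALSE)
  oc <- outcome_column(schema)
  y <- table[, oc]
  vals <- numeric(0)
  for (cs in schema$columns) {
    v <- table[, cs$name]
    vals <- c(vals, min(v), max(v), mean(v))
    if (cs$is_outcome) {
      vals <- c(vals, mean(y))
    } else if (!is.null(cs$risky_threshold)) {
      flags <- if (cs$risky_direction == "above") v > cs$risky_threshold
               else v < cs$risky_threshold
      vals <- c(vals, mean(flags), compute_odds_ratio(flags, y))
    }
  }
  new_stats_vector(vals, schema)
}

#' Validate a statistics vector against its schema
#'
#' Checks the structural invariants: complete menu coverage, per-column
#' `min <= mean <= max`, fractions and prevalence in `[0, 1]`, odds ratios
#' non-negative. Violations are returned, not raised, so callers can report
#' all of them at once.
#'
#' @param stats A `stats_vector` (or named numeric vector in menu order).
#' @param schema The schema to validate against.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_statistics <- function(stats, schema = attr(stats, "schema")) {
  stopifnot(inherits(schema, "table_schema"))
  nm <- stat_names(schema)
  out <- character(0)
  if (length(stats) != length(nm) || !identical(names(stats), nm))
    return(paste0("statistics names/order do not match the schema menu (",
                  length(stats), " entries, expected ", length(nm), ")"))
  v <- as.numeric(stats)
  names(v) <- nm
  if (any(!is.finite(v)))
    out <- c(out, paste0("non-finite value for ",
                         paste(nm[!is.finite(v)], collapse = ", ")))
  menu <- stat_menu(schema)
  for (col in unique(menu$column)) {
    g <- function(st) {
      k <- paste0(col, "__", st)
      if (k %in% nm) v[[k]] else NULL
    }
    mn <- g("min"); mx <- g("max"); me <- g("mean")
    if (is.finite(mn) && is.finite(mx) && mn > mx + 1e-12)
      out <- c(out, paste0("column '", col, "': min > max"))
    if (is.finite(me) && is.finite(mn) && is.finite(mx) &&
        (me < mn - 1e-12 || me > mx + 1e-12))
      out <- c(out, paste0("column '", col, "': mean outside [min, max]"))
    for (st in c("risky_fraction", "prevalence")) {
      f <- g(st)
      if (!is.null(f) && is.finite(f) && (f < 0 || f > 1))
        out <- c(out, paste0("column '", col, "': ", st, " outside [0, 1]"))
    }
    or <- g("odds_ratio")
    if (!is.null(or) && is.finite(or) && or < 0)
      out <- c(out, paste0("column '", col, "': negative odds ratio"))
  }
  out
}

#' Perturb a statistics vector
#'
#' Replaces every value v by v * (1 + u) with u drawn uniformly from
#' `[-amplitude, +amplitude]` (independently per entry), then repairs the
#' vector so the structural invariants still hold: fractions and prevalence
#' are clipped to `[0, 1]`, binary-column range statistics to `[0, 1]`, and
#' each column's mean is clipped into its (possibly perturbed) `[min, max]`.
#' Used to build training-corpus diversity around a base statistics vector.
#'
#' @param stats A `stats_vector`.
#' @param amplitude Relative perturbation half-width (default 0.01, i.e. a
#'   plus/minus 1 percent envelope).
#' @param seed Integer seed; same seed and input give identical output.
#' @return A repaired `stats_vector`.
#' @export
perturb_statistics <- function(stats, amplitude = 0.01, seed = 1L) {
  schema <- attr(stats, "schema")
  stopifnot(inherits(schema, "table_schema"), amplitude >= 0)
  v <- as.numeric(stats)
  u <- with_seed(seed, stats::runif(length(v), -amplitude, amplitude))
  v <- v * (1 + u)
  repair_statistics(new_stats_vector(v, schema))
}

repair_statistics <- function(stats) {
  schema <- attr(stats, "schema")
  v <- as.numeric(stats)
  names(v) <- names(stats)
  idx <- function(col, st) match(paste0(col, "__", st), names(v))
  for (cs in schema$columns) {
    col <- cs$name
    i_mn <- idx(col, "min"); i_mx <- idx(col, "max"); i_me <- idx(col, "mean")
    if (cs$kind == "binary") {
      v[i_me] <- min(max(v[i_me], 0), 1)
      # binary range statistics can only be 0 or 1
      v[i_mn] <- round(min(max(v[i_mn], 0), 1))
      v[i_mx] <- round(min(max(v[i_mx], 0), 1))
    }
    if (v[i_mn] > v[i_mx]) {
      mid <- (v[i_mn] + v[i_mx]) / 2
      v[i_mn] <- mid; v[i_mx] <- mid
    }
    for (st in c("risky_fraction", "prevalence")) {
      i <- idx(col, st)
      if (!is.na(i)) v[i] <- min(max(v[i], 0), 1)
    }
    # a binary outcome's mean IS its prevalence; keep them consistent
    i_pr <- idx(col, "prevalence")
    if (!is.na(i_pr)) v[i_me] <- v[i_pr]
    v[i_me] <- min(max(v[i_me], v[i_mn]), v[i_mx])
    i_or <- idx(col, "odds_ratio")
    if (!is.na(i_or)) v[i_or] <- max(v[i_or], 0)
  }
  new_stats_vector(v, schema)
}

#' Read / write statistics vectors as CSV
#'
#' One header row of `<column>__<statistic>` names, one row per statistics
#' vector. Values round-trip losslessly to at least 10 significant digits.
#'
#' @param stats_list A `stats_vector` or list of them (all on one schema).
#' @param path File path.
#' @return `write_statistics_csv()` returns `path` invisibly;
#'   `read_statistics_csv()` returns a list of `stats_vector`s.
#' @export
write_statistics_csv <- function(stats_list, path) {
  if (inherits(stats_list, "stats_vector")) stats_list <- list(stats_list)
  schema <- attr(stats_list[[1L]], "schema")
  nm <- stat_names(schema)
  m <- do.call(rbind, lapply(stats_list, function(s) {
    stopifnot(identical(names(s), nm))
    as.numeric(s)
  }))
  df <- as.data.frame(m)
  names(df) <- nm
  df[] <- lapply(df, function(v) formatC(v, format = "g", digits = 15))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_statistics_csv
#' @param schema Schema whose menu the CSV columns must match.
#' @export
read_statistics_csv <- function(path, schema) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- stat_names(schema)
  if (!identical(names(df), nm))
    stop("statistics CSV header does not match the schema menu", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) new_stats_vector(as.numeric(df[i, ]), schema))
}

# Map a statistics vector to [0,1]-scale conditioning inputs for the networks:
# range statistics are min-max scaled by the schema column range, fractions are
# already in [0,1], odds ratios are squashed by or/(1+or).
normalize_statistics <- function(stats, schema = attr(stats, "schema")) {
  menu <- stat_menu(schema)
  v <- as.numeric(stats)
  out <- numeric(length(v))
  for (k in seq_along(v)) {
    col <- menu$column[k]; st <- menu$statistic[k]
    cs <- schema$columns[[col]]
    out[k] <- switch(st,
      min = , max = , mean = {
        rng <- cs$max_value - cs$min_value
        if (rng <= 0) 0 else (v[k] - cs$min_value) / rng
      },
      risky_fraction = , prevalence = v[k],
      odds_ratio = v[k] / (1 + v[k])
    )
  }
  out
}
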