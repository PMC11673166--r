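#' Synthesize a random table matching a target statistics vector
#'
#' Builds a patient-level table whose extracted statistics approximate a
#' target vector. The sampling law is deliberately simple and auditable
#' against [extract_statistics()]:
#' \enumerate{
#'   \item the outcome column gets `round(prevalence * n_rows)` cases
#'     (clamped so both classes keep at least one row);
#'   \item per feature column with a risk threshold, the risky count is
#'     `round(risky_fraction * n_rows)` (banker's rounding); how the risky
#'     rows split between cases and controls is chosen by integer search over
#'     the 2x2 contingency layouts to best match the target odds ratio
#'     (on the log scale, with 0.5 continuity correction while scoring);
#'   \item cells are sampled uniformly inside the risky / non-risky
#'     sub-ranges of `[min, max]`, then an iterative shift-and-clip adjusts
#'     the column mean toward the target while every cell stays inside its
#'     sub-range (so risky counts are preserved); count columns are rounded
#'     to integers and fine-tuned by unit steps.
#' }
#' The target min/max act as sampling bounds, so the extracted min/max never
#' exceed them; the extracted mean lands within 1 percent of the schema
#' column range of the target (when achievable given the bounds); the risky
#' fraction is exact to within `1/n_rows`.
#'
#' @param target A valid `stats_vector` for `schema`.
#' @param schema A [table_schema()].
#' @param n_rows Number of patient rows (default: the schema's).
#' @param seed Integer seed; the construction is deterministic given it.
#' @param mean_tol Mean-matching tolerance as a fraction of the schema column
#'   range (default 0.01).
#' @return A [new_table()] object.
#' @export
synthesize_table <- function(target, schema = attr(target, "schema"),
                             n_rows = schema$n_rows_default, seed = 1L,
                             mean_tol = 0.01) {
  viol <- validate_statistics(target, schema)
  if (length(viol))
    stop("invalid target statistics: ", paste(viol, collapse = "; "),
         call. = FALSE)
  n_rows <- as.integer(n_rows)
  if (n_rows < 2L) stop("'n_rows' must be at least 2", call. = FALSE)
  tv <- as.numeric(target); names(tv) <- names(target)
  g <- function(col, st) tv[[paste0(col, "__", st)]]

  with_seed(seed, {
    oc <- outcome_column(schema)
    prev <- g(oc, "prevalence")
    n_case <- min(max(round(prev * n_rows), 1L), n_rows - 1L)
    y <- c(rep(1, n_case), rep(0, n_rows - n_case))
    case_idx <- seq_len(n_case)
    ctrl_idx <- seq.int(n_case + 1L, n_rows)

    cols <- schema_columns(schema)
    out <- matrix(NA_real_, n_rows, length(cols), dimnames = list(NULL, cols))
    out[, oc] <- y

    for (cs in schema$columns) {
      if (cs$is_outcome) next
      col <- cs$name
      lo <- max(g(col, "min"), cs$min_value)
      hi <- min(g(col, "max"), cs$max_value)
      if (lo > hi) { mid <- (lo + hi) / 2; lo <- mid; hi <- mid }
      tmean <- g(col, "mean")
      if (tmean < lo - 1e-9 || tmean > hi + 1e-9)
        stop("infeasible target for column '", col,
             "': mean outside [min, max]", call. = FALSE)
      tmean <- min(max(tmean, lo), hi)

      if (is.null(cs$risky_threshold)) {
        risky <- rep(FALSE, n_rows)
        bounds_lo <- rep(lo, n_rows); bounds_hi <- rep(hi, n_rows)
      } else {
        thr <- cs$risky_threshold
        up <- cs$risky_direction == "above"
        # feasible risky / non-risky sub-ranges inside [lo, hi]
        r_lo <- if (up) max(thr, lo) else lo
        r_hi <- if (up) hi else min(thr, hi)
        nr_lo <- if (up) lo else max(thr, lo)
        nr_hi <- if (up) min(thr, hi) else hi
        risky_possible <- if (up) hi > thr else lo < thr
        nonrisky_possible <- if (up) lo <= thr else hi >= thr
        f <- g(col, "risky_fraction")
        n_risky <- round(f * n_rows)
        if (!risky_possible) n_risky <- 0L
        if (!nonrisky_possible) n_risky <- n_rows
        n_risky <- as.integer(min(max(n_risky, 0L), n_rows))

        # split risky rows between cases and controls to approximate the OR
        or_t <- g(col, "odds_ratio")
        a_min <- max(0L, n_risky - length(ctrl_idx))
        a_max <- min(n_risky, n_case)
        a_cand <- seq.int(a_min, a_max)
        score <- vapply(a_cand, function(a) {
          b <- n_risky - a; c_ <- n_case - a; d <- length(ctrl_idx) - b
          or_a <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
          abs(log(or_a) - log(max(or_t, 1e-12)))
        }, numeric(1))
        a <- a_cand[which.min(score)]
        b <- n_risky - a
        risky <- rep(FALSE, n_rows)
        if (a > 0L) risky[case_idx[sample.int(length(case_idx), a)]] <- TRUE
        if (b > 0L) risky[ctrl_idx[sample.int(length(ctrl_idx), b)]] <- TRUE

        # strict inequality at the threshold: shave eps off the risky side
        eps <- 1e-9 * (hi - lo + 1)
        bounds_lo <- ifelse(risky, if (up) r_lo + eps else r_lo, nr_lo)
        bounds_hi <- ifelse(risky, if (up) r_hi else r_hi - eps, nr_hi)
        if (cs$kind == "count") {
          bounds_lo <- ifelse(risky & up, floor(thr) + 1, ceiling(bounds_lo))
          bounds_hi <- ifelse(risky & !up, ceiling(thr) - 1, floor(bounds_hi))
        }
        if (any(bounds_lo > bounds_hi + 1e-12))
          stop("infeasible risky sub-range for column '", col, "'",
               call. = FALSE)
      }

      v <- stats::runif(n_rows, bounds_lo, bounds_hi)
      v <- adjust_mean(v, tmean, bounds_lo, bounds_hi,
                       tol = mean_tol * (cs$max_value - cs$min_value),
                       integer_valued = cs$kind == "count")
      out[, col] <- v
    }
    new_table(out, schema)
  })
}

# Iterative shift-and-clip toward a target mean with per-cell box constraints;
# integer columns are rounded and then fine-tuned by unit steps on cells with
# slack. Converges to the nearest achievable mean.
adjust_mean <- function(v, target, lo, hi, tol, integer_valued = FALSE,
                        max_iter = 200L) {
  n <- length(v)
  for (it in seq_len(max_iter)) {
    delta <- target - mean(v)
    if (abs(delta) <= tol * 0.5) break
    v <- pmin(pmax(v + delta, lo), hi)
    if (all(v >= hi - 1e-12) || all(v <= lo + 1e-12)) break
  }
  if (integer_valued) {
    v <- pmin(pmax(round(v), ceiling(lo - 1e-9)), floor(hi + 1e-9))
    need <- round((target - mean(v)) * n)
    step <- sign(need)
    k <- abs(need)
    while (k > 0L) {
      idx <- if (step > 0) which(v + 1 <= hi + 1e-9) else which(v - 1 >= lo - 1e-9)
      if (!length(idx)) break
      take <- idx[seq_len(min(k, length(idx)))]
      v[take] <- v[take] + step
      k <- k - length(take)
    }
  }
  v
}

#' Synthetic diabetes-cohort reference table
#'
#' Deterministically generates a plausible patient-level table for a schema —
#' by default 766 rows by 9 columns emulating a small diabetes cohort. Each
#' feature is drawn from a class-conditional distribution (cases shifted
#' toward the risky end of the column range), clipped to the column bounds,
#' with count columns rounded. This fixture stands in for a real cohort as
#' the evaluation ground truth; it is entirely synthetic.
#'
#' @param schema A [table_schema()] (default [pima_schema()]).
#' @param seed Integer seed.
#' @param prevalence Outcome prevalence (default 0.35).
#' @return A [new_table()] object with `schema$n_rows_default` rows.
#' @export
make_reference_table <- function(schema = pima_schema(), seed = 20L,
                                 prevalence = 0.35) {
  with_seed(seed, {
    n <- schema$n_rows_default
    n_case <- min(max(round(prevalence * n), 1L), n - 1L)
    y <- sample(c(rep(1, n_case), rep(0, n - n_case)))
    cols <- schema_columns(schema)
    out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
    oc <- outcome_column(schema)
    out[, oc] <- y
    for (cs in schema$columns) {
      if (cs$is_outcome) next
      rng <- cs$max_value - cs$min_value
      mu0 <- cs$min_value + 0.30 * rng   # controls
      mu1 <- cs$min_value + 0.45 * rng   # cases: shifted toward risk
      sd_ <- 0.16 * rng
      v <- ifelse(y == 1, stats::rnorm(n, mu1, sd_), stats::rnorm(n, mu0, sd_))
      v <- pmin(pmax(v, cs$min_value), cs$max_value)
      if (cs$kind == "count") v <- round(v)
      out[, cs$name] <- v
    }
    new_table(out, schema)
  })
}

#' Build the paired (statistics, table) training corpus
#'
#' Step one of the pipeline: starting from a base statistics vector,
#' `n_tables` perturbed vectors are drawn ([perturb_statistics()], default
#' plus/minus 1 percent), one table is synthesized per perturbed vector
#' ([synthesize_table()]), and the statistics CSV is re-extracted from the
#' actual tables, so row `i` of the CSV equals
#' `extract_statistics(table_i)` at serialization precision. Tables are
#' written one per CSV file; a YAML manifest records the pairing order.
#'
#' @param base Base `stats_vector` (typically extracted from a reference
#'   table that is itself held out of the corpus).
#' @param schema The table schema.
#' @param n_tables Number of (statistics, table) pairs (default 10000).
#' @param amplitude Perturbation envelope (default 0.01).
#' @param seed Master seed; all per-table seeds derive from it.
#' @param out_dir Output directory (created if needed).
#' @param n_rows Rows per table (default: the schema's).
#' @return An object of class `"training_corpus"`: `dir`, `table_paths`,
#'   `stats_path`, `stats` (list of `stats_vector`s), `schema`, `n_tables`.
#' @export
build_training_corpus <- function(base, schema = attr(base, "schema"),
                                  n_tables = 10000L, amplitude = 0.01,
                                  seed = 1L, out_dir,
                                  n_rows = schema$n_rows_default) {
  stopifnot(n_tables >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table_paths <- character(n_tables)
  stats_list <- vector("list", n_tables)
  for (i in seq_len(n_tables)) {
    res <- tryCatch({
      si <- perturb_statistics(base, amplitude,
                               seed = derive_seed(seed, paste0("perturb", i)))
      tb <- synthesize_table(si, schema, n_rows = n_rows,
                             seed = derive_seed(seed, paste0("table", i)))
      list(stats = extract_statistics(tb, schema), table = tb)
    }, error = function(e)
      stop("corpus synthesis failed at table ", i, ": ", conditionMessage(e),
           call. = FALSE))
    p <- file.path(out_dir, sprintf("table_%05d.csv", i))
    write_table_csv(res$table, p)
    table_paths[i] <- p
    stats_list[[i]] <- res$stats
  }
  stats_path <- file.path(out_dir, "statistics.csv")
  write_statistics_csv(stats_list, stats_path)
  write_schema(schema, file.path(out_dir, "schema.yaml"))
  yaml::write_yaml(list(n_tables = n_tables, amplitude = amplitude,
                        seed = as.integer(seed), n_rows = as.integer(n_rows),
                        tables = basename(table_paths),
                        statistics = "statistics.csv",
                        schema = "schema.yaml"),
                   file.path(out_dir, "manifest.yaml"))
  structure(list(dir = out_dir, table_paths = table_paths,
                 stats_path = stats_path, stats = stats_list,
                 schema = schema, n_tables = as.integer(n_tables),
                 n_rows = as.integer(n_rows)),
            class = "training_corpus")
}

#' Reload a training corpus from its manifest
#' @param dir Directory written by [build_training_corpus()].
#' @return A `training_corpus` object.
#' @export
read_corpus <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  schema <- read_schema(file.path(dir, man$schema))
  stats_list <- read_statistics_csv(file.path(dir, man$statistics), schema)
  structure(list(dir = dir,
                 table_paths = file.path(dir, man$tables),
                 stats_path = file.path(dir, man$statistics),
                 stats = stats_list, schema = schema,
                 n_tables = as.integer(man$n_tables),
                 n_rows = as.integer(man$n_rows)),
            class = "training_corpus")
}

#' @export
print.training_corpus <- function(x, ...) {
  cat("training_corpus:", x$n_tables, "paired (statistics, table) samples,",
      x$n_rows, "rows x", length(schema_columns(x$schema)), "columns\n")
  cat("  dir:", x$dir, "\n")
  invisible(x)
}
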