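#' Row and column sums of a table matrix
#'
#' The table-similarity loss is built from row sums (one per patient; row
#' order must not matter, so rows are compared through their sums) and column
#' sums (one per feature).
#'
#' @param table Non-empty numeric matrix.
#' @return Numeric vector of length `nrow(table)` (`row_sums`) or
#'   `ncol(table)` (`column_sums`).
#' @export
row_sums <- function(table) {
  table <- as.matrix(table)
  if (length(table) == 0L) stop("matrix must be non-empty", call. = FALSE)
  rowSums(table)
}

#' @rdname row_sums
#' @export
column_sums <- function(table) {
  table <- as.matrix(table)
  if (length(table) == 0L) stop("matrix must be non-empty", call. = FALSE)
  colSums(table)
}

#' Table-similarity loss breakdown for one real/synthetic pair
#'
#' Compares two same-shaped tables row-wise, not cell-wise, so the loss is
#' invariant under row permutation of either table. The computation:
#' \enumerate{
#'   \item row sums `r` (real) and `s` (synthetic), column sums `R` and `S`;
#'   \item vertical term: `mu = mean(|R_m - S_m|)` over columns (paired by
#'     column index; absolute value by default so the loss stays
#'     non-negative);
#'   \item for every real row sum, the minimum absolute difference to any
#'     synthetic row sum: `delta_n = min_i |r_n - s_i|`;
#'   \item `N` = number of `delta` entries whose value (rounded to
#'     `equality_decimals`) occurs at least twice; repeated-minimum fraction
#'     `P = N / n_rows`;
#'   \item `nu = mean(delta)`; horizontal term `D = nu * P`;
#'   \item per-sample loss `L = D + mu`.
#' }
#' Identical tables give `mu = 0`, all `delta = 0`, `N = n_rows`, `P = 1`,
#' `nu = D = L = 0`.
#'
#' @param real,synth Numeric matrices of identical shape (rows = patients).
#' @param equality_decimals Decimal places used when testing `delta` values
#'   for equality (default 6).
#' @param signed If `TRUE`, use signed column differences `mean(R - S)` for
#'   `mu` (the literal textbook form); the default `FALSE` uses absolute
#'   differences, which guarantees `L >= 0`.
#' @return A list of class `"ts_breakdown"` with fields `r`, `s`, `R`, `S`,
#'   `mu`, `delta`, `N`, `P`, `nu`, `D`, `L`.
#' @export
ts_components <- function(real, synth, equality_decimals = 6L, signed = FALSE) {
  real <- as.matrix(real); synth <- as.matrix(synth)
  if (!all(dim(real) == dim(synth)))
    stop("'real' and 'synth' must have identical shape", call. = FALSE)
  n_rows <- nrow(real); n_cols <- ncol(real)
  r <- row_sums(real); s <- row_sums(synth)
  R <- column_sums(real); S <- column_sums(synth)
  mu <- if (signed) mean(R - S) else mean(abs(R - S))
  # delta_n = min_i |r_n - s_i|, via the full |r x s| difference matrix
  dmat <- abs(outer(r, s, "-"))
  delta <- apply(dmat, 1L, min)
  key <- round(delta, equality_decimals)
  tab <- table(key)
  N <- sum(tab[tab >= 2L])
  P <- N / n_rows
  nu <- mean(delta)
  D <- nu * P
  structure(list(r = r, s = s, R = R, S = S, mu = mu, delta = delta,
                 N = as.integer(N), P = P, nu = nu, D = D, L = D + mu),
            class = "ts_breakdown")
}

#' @export
print.ts_breakdown <- function(x, ...) {
  cat("Table-similarity breakdown\n")
  cat(sprintf("  vertical term    mu = %.6g\n", x$mu))
  cat(sprintf("  repeated minima  N  = %d of %d (P = %.4f)\n",
              x$N, length(x$delta), x$P))
  cat(sprintf("  minima mean      nu = %.6g\n", x$nu))
  cat(sprintf("  horizontal term  D  = %.6g\n", x$D))
  cat(sprintf("  sample loss      L  = %.6g\n", x$L))
  invisible(x)
}

#' Batch table-similarity loss
#'
#' Mean of the per-pair sample losses `L`, with (by default) a square root on
#' the batch mean. Zero exactly when every pair is identical.
#'
#' @param pairs Non-empty list; each element a list/pair of two same-shaped
#'   matrices `(real, synth)`.
#' @param apply_sqrt Take the square root of the batch mean (default `TRUE`).
#' @param equality_decimals Passed to [ts_components()].
#' @return Non-negative scalar loss.
#' @export
ts_batch_loss <- function(pairs, apply_sqrt = TRUE, equality_decimals = 6L) {
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("'pairs' must be a non-empty list", call. = FALSE)
  L <- vapply(pairs, function(p)
    ts_components(p[[1L]], p[[2L]], equality_decimals)$L, numeric(1))
  m <- mean(L)
  if (apply_sqrt) sqrt(m) else m
}

# Gradient of the per-sample loss L = D + mu with respect to the synthetic
# table entries. The repeated-minimum fraction P is a piecewise-constant count
# and is treated as a per-evaluation constant; the argmin in delta_n is fixed
# at the current point (first index on ties).
#   d mu / d y_im   = sign(S_m - R_m) / n_cols
#   d nu / d y_ij   = (1/n_rows) * sum_{n: argmin_n = i} sign(s_i - r_n)
# Returns list(grad = matrix like synth, L = sample loss).
ts_sample_gradient <- function(real, synth, equality_decimals = 6L) {
  n_rows <- nrow(real); n_cols <- ncol(real)
  r <- rowSums(real); s <- rowSums(synth)
  R <- colSums(real); S <- colSums(synth)
  mu <- mean(abs(R - S))
  dmat <- abs(outer(r, s, "-"))
  amin <- apply(dmat, 1L, which.min)
  delta <- dmat[cbind(seq_len(n_rows), amin)]
  key <- round(delta, equality_decimals)
  tab <- table(key)
  P <- sum(tab[tab >= 2L]) / n_rows
  nu <- mean(delta)
  L <- nu * P + mu
  grad <- matrix(rep(sign(S - R) / n_cols, each = n_rows), n_rows, n_cols)
  if (P > 0) {
    drow <- numeric(n_rows)  # d nu / d s_i, aggregated over argmin hits
    sgn <- sign(s[amin] - r)
    for (n in seq_len(n_rows)) drow[amin[n]] <- drow[amin[n]] + sgn[n]
    grad <- grad + (P / n_rows) * matrix(drow, n_rows, n_cols)
  }
  list(grad = grad, L = L)
}
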