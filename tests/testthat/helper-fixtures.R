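# Shared fixtures, built in code.

# Small three-column schema used wherever full scale is unnecessary.
tiny_schema <- function(n_rows = 50L) {
  table_schema(list(
    column_spec("Marker", "continuous", 0, 10,
                risky_threshold = 7, risky_direction = "above"),
    column_spec("Score", "continuous", 0, 100,
                risky_threshold = 60, risky_direction = "above"),
    column_spec("Outcome", "binary", 0, 1, is_outcome = TRUE)
  ), n_rows_default = n_rows)
}

tiny_generator_config <- function(schema, n_rows = schema$n_rows_default) {
  generator_config(stat_dim = length(stat_menu(schema)$column),
                   noise_dim = 16L, layer_widths = c(32L, 32L),
                   reinjection_layer = 2L,
                   output_shape = c(n_rows, length(schema_columns(schema))))
}

tiny_discriminator_config <- function() {
  discriminator_config(layer_widths = c(64L, 32L), stat_injection_layer = 1L)
}

# Straight-line loop transcription of the table-similarity recipe, kept
# deliberately independent of the vectorized implementation.
ts_oracle <- function(R, S, dec = 6L) {
  n <- nrow(R); m <- ncol(R)
  r <- vapply(seq_len(n), function(i) sum(R[i, ]), numeric(1))
  s <- vapply(seq_len(n), function(i) sum(S[i, ]), numeric(1))
  Rm <- vapply(seq_len(m), function(j) sum(R[, j]), numeric(1))
  Sm <- vapply(seq_len(m), function(j) sum(S[, j]), numeric(1))
  mu <- mean(abs(Rm - Sm))
  delta <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (k in seq_len(n)) best <- min(best, abs(r[i] - s[k]))
    delta[i] <- best
  }
  key <- round(delta, dec)
  N <- 0L
  for (i in seq_len(n)) if (sum(key == key[i]) >= 2L) N <- N + 1L
  P <- N / n
  nu <- mean(delta)
  D <- nu * P
  list(mu = mu, N = N, P = P, nu = nu, D = D, L = D + mu)
}

# Binary flag vectors realizing a given 2x2 layout (a = risky & case, ...).
flags_from_cells <- function(a, b, c_, d) {
  risky <- c(rep(1, a + b), rep(0, c_ + d))
  outcome <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
  list(risky = risky, outcome = outcome)
}
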