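#' Bundled benchmark evaluation results
#'
#' Small plain-text tables of reported evaluation results for four tabular
#' generators (a statistics-conditioned GAN, Gaussian multivariate modelling,
#' the Synthetic Data Vault, and CTGAN) on a diabetes cohort table. They are
#' inputs for worked examples and regression checks of the evaluation
#' machinery — applying the 0.05 p-value rule, the 0.1 Wasserstein threshold
#' and the resemblance aggregation to these tables must reproduce the
#' reported verbal labels.
#'
#' @param which One of `"ttest"` (per-feature t-test p-values),
#'   `"chisq"` (outcome chi-square p-values), `"wasserstein"` (per-feature
#'   normalized distances), `"fidelity_labels"` (per-metric labels and
#'   totals), `"utility"` (TRTR/TSTR classifier metrics).
#' @return A data frame.
#' @export
benchmark_results <- function(which = c("ttest", "chisq", "wasserstein",
                                        "fidelity_labels", "utility")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("benchmark_", which, ".csv"),
                      package = "statgan", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
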