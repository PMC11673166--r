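#' Configure an end-to-end pipeline run
#'
#' Bundles every knob of the corpus -> train -> generate -> evaluate pipeline.
#' A single master seed deterministically derives one seed per stage, so a
#' run is reproducible from its config alone.
#'
#' @param out_dir Output directory for all artifacts.
#' @param schema Table schema (default [pima_schema()]).
#' @param n_rows Rows per table (default: the schema's).
#' @param n_tables Training pairs (default 10000).
#' @param amplitude Statistics perturbation envelope (default 0.01).
#' @param generator,discriminator,control Network/training configurations
#'   (defaults as in [tsgan()]).
#' @param master_seed Single seed from which all stage seeds derive.
#' @param fidelity,utility Toggle the evaluation stages.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir, schema = pima_schema(),
                       n_rows = schema$n_rows_default,
                       n_tables = 10000L, amplitude = 0.01,
                       generator = NULL,
                       discriminator = discriminator_config(),
                       control = train_config(),
                       master_seed = 1L,
                       fidelity = TRUE, utility = TRUE) {
  structure(list(out_dir = out_dir, schema = schema,
                 n_rows = as.integer(n_rows), n_tables = as.integer(n_tables),
                 amplitude = amplitude, generator = generator,
                 discriminator = discriminator, control = control,
                 master_seed = as.integer(master_seed),
                 fidelity = isTRUE(fidelity), utility = isTRUE(utility)),
            class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes, with per-stage logging and per-stage seeds derived from the
#' master seed: build the reference table fixture -> extract its statistics
#' (the reference table and its statistics are held out as ground truth and
#' never enter the training corpus) -> build the perturbed-statistics corpus
#' -> train the GAN -> generate a table conditioned on the held-out base
#' statistics -> fidelity and utility reports against the reference table.
#' Every artifact lands under `config$out_dir` and is listed in
#' `manifest.yaml`.
#'
#' @param config A [run_config()].
#' @return A list of class `"pipeline_run"`: `reference`, `base_stats`,
#'   `corpus`, `fit`, `generated`, `fidelity`, `utility`, `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ms <- config$master_seed
  stage <- function(name, expr) {
    message(sprintf("[%s] starting", name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  reference <- stage("reference", make_reference_table(
    config$schema, seed = derive_seed(ms, "reference")))
  ref_path <- file.path(out, "reference_table.csv")
  write_table_csv(reference, ref_path)
  base_stats <- extract_statistics(reference, config$schema)
  stats_path <- file.path(out, "base_statistics.csv")
  write_statistics_csv(base_stats, stats_path)

  corpus <- stage("corpus", build_training_corpus(
    base_stats, config$schema, n_tables = config$n_tables,
    amplitude = config$amplitude, seed = derive_seed(ms, "corpus"),
    out_dir = file.path(out, "corpus"), n_rows = config$n_rows))

  control <- config$control
  control$seed <- derive_seed(ms, "train")
  fit <- stage("train", tsgan(corpus, generator = config$generator,
                              discriminator = config$discriminator,
                              control = control))
  hist_path <- file.path(out, "loss_history.csv")
  utils::write.csv(fit$history, hist_path, row.names = FALSE)
  ckpt_path <- file.path(out, "checkpoint.rds")
  saveRDS(fit, ckpt_path)

  generated <- stage("generate", generate_table(
    fit, base_stats, config$schema, seed = derive_seed(ms, "generate")))
  gen_path <- file.path(out, "generated_table.csv")
  write_table_csv(generated, gen_path)

  fid <- uti <- NULL
  fid_path <- uti_path <- NULL
  if (config$fidelity) {
    fid <- stage("fidelity", fidelity_report(reference, generated,
                                             config$schema))
    fid_path <- file.path(out, "fidelity_report.csv")
    write_report_csv(fid, fid_path)
  }
  if (config$utility) {
    uti <- stage("utility", run_tstr_trtr(
      reference, generated, split_seed = derive_seed(ms, "split")))
    uti_path <- file.path(out, "utility_report.csv")
    write_report_csv(uti, uti_path)
  }

  manifest <- list(
    master_seed = ms,
    n_tables = config$n_tables, n_rows = config$n_rows,
    amplitude = config$amplitude,
    reference_table = basename(ref_path),
    base_statistics = basename(stats_path),
    corpus_dir = "corpus",
    checkpoint = basename(ckpt_path),
    loss_history = basename(hist_path),
    generated_table = basename(gen_path),
    fidelity_report = if (!is.null(fid_path)) basename(fid_path),
    utility_report = if (!is.null(uti_path)) basename(uti_path),
    fidelity_ura = if (!is.null(fid)) fid$ura,
    utility_label = if (!is.null(uti)) utility_label(uti))
  manifest_path <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)

  structure(list(reference = reference, base_stats = base_stats,
                 corpus = corpus, fit = fit, generated = generated,
                 fidelity = fid, utility = uti,
                 manifest_path = manifest_path, out_dir = out),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n")
  cat("  corpus:", x$corpus$n_tables, "pairs\n")
  cat("  training:", x$fit$n_iterations, "iterations\n")
  if (!is.null(x$fidelity)) cat("  fidelity URA:", x$fidelity$ura, "\n")
  if (!is.null(x$utility))
    cat("  utility label:", utility_label(x$utility), "\n")
  invisible(x)
}
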