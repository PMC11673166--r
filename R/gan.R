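#' Generator configuration
#'
#' The generator maps (random noise, statistics vector) to a whole normalized
#' table in one forward pass. The statistics are injected twice: concatenated
#' to the noise at the input, and concatenated again to the hidden activation
#' after `reinjection_layer` layers, which refocuses the network on the
#' conditioning information once it has started to reconstruct table
#' structure. Injecting after two layers (the default) avoids the very wide
#' first layer that immediate re-injection would require.
#'
#' @param stat_dim Length of the conditioning statistics vector.
#' @param noise_dim Noise dimension (default 128).
#' @param layer_widths Hidden fully connected layer widths.
#' @param reinjection_layer Hidden layer after which statistics are injected
#'   again (default 2; must be < number of layers).
#' @param output_shape `(n_rows, n_cols)` of the generated table
#'   (default `c(766, 9)`).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(stat_dim, noise_dim = 128L,
                             layer_widths = c(128L, 256L, 512L),
                             reinjection_layer = 2L,
                             output_shape = c(766L, 9L)) {
  stopifnot(stat_dim >= 1L, noise_dim >= 1L, length(layer_widths) >= 1L,
            all(layer_widths >= 1L), all(output_shape >= 1L),
            length(output_shape) == 2L)
  n_layers <- length(layer_widths) + 1L  # + output layer
  if (reinjection_layer < 1L || reinjection_layer >= n_layers)
    stop("'reinjection_layer' must lie strictly before the final layer",
         call. = FALSE)
  structure(list(stat_dim = as.integer(stat_dim),
                 noise_dim = as.integer(noise_dim),
                 layer_widths = as.integer(layer_widths),
                 reinjection_layer = as.integer(reinjection_layer),
                 output_shape = as.integer(output_shape)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' The discriminator scores a (flattened, normalized) table as real vs
#' generated. The conditioning statistics are concatenated to the feature map
#' once the network reaches `stat_injection_layer`, so the score is judged
#' against the statistics the table claims to follow.
#'
#' @param layer_widths Hidden fully connected layer widths.
#' @param stat_injection_layer Hidden layer after which the statistics are
#'   concatenated (default: mid-network).
#' @return A list of class `"discriminator_config"`.
#' @export
discriminator_config <- function(layer_widths = c(512L, 256L, 128L),
                                 stat_injection_layer = 2L) {
  stopifnot(length(layer_widths) >= 1L, all(layer_widths >= 1L))
  n_layers <- length(layer_widths) + 1L
  if (stat_injection_layer < 1L || stat_injection_layer >= n_layers)
    stop("'stat_injection_layer' must lie strictly before the final layer",
         call. = FALSE)
  structure(list(layer_widths = as.integer(layer_widths),
                 stat_injection_layer = as.integer(stat_injection_layer)),
            class = "discriminator_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with a generator
#' learning rate of 1e-4 and a discriminator learning rate of 5e-5 (the 2:1
#' asymmetry mitigates mode collapse), batch size 64 with incomplete trailing
#' batches dropped, 70 epochs, and a per-epoch scatter snapshot of the fifth
#' and seventh feature columns for visual monitoring.
#'
#' @param lr_generator,lr_discriminator Adam learning rates.
#' @param batch_size Mini-batch size (pairs per iteration).
#' @param max_epochs Number of epochs; training always runs to this point
#'   (quality-based early stopping is left to the analyst via the history).
#' @param drop_last_batch Drop the final incomplete batch each epoch
#'   (default `TRUE`), so iterations per epoch = `floor(n_pairs / batch_size)`.
#' @param seed Integer seed driving shuffling and noise.
#' @param monitor_feature_pair Two column indices whose joint scatter is
#'   snapshotted once per epoch (default `c(5, 7)`).
#' @param adam_beta1,adam_beta2 Adam moment decay rates (0.5, 0.999 — the
#'   usual GAN-stabilizing choice).
#' @param verbose Print a line per epoch.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(lr_generator = 1e-4, lr_discriminator = 5e-5,
                         batch_size = 64L, max_epochs = 70L,
                         drop_last_batch = TRUE, seed = 1L,
                         monitor_feature_pair = c(5L, 7L),
                         adam_beta1 = 0.5, adam_beta2 = 0.999,
                         verbose = FALSE) {
  stopifnot(lr_generator > 0, lr_discriminator > 0, batch_size >= 1L,
            max_epochs >= 1L, length(monitor_feature_pair) == 2L)
  structure(list(lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 drop_last_batch = isTRUE(drop_last_batch),
                 seed = as.integer(seed),
                 monitor_feature_pair = as.integer(monitor_feature_pair),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Iteration arithmetic under drop-last batching
#'
#' With incomplete trailing batches dropped, an epoch over `n_pairs` training
#' pairs at batch size `b` contributes `floor(n_pairs / b)` iterations; the
#' cumulative count after `epochs` epochs is `epochs * floor(n_pairs / b)`
#' (e.g. 10,000 pairs at batch 64 give 156 iterations per epoch and 10,920
#' by the end of epoch 70).
#'
#' @param n_pairs Number of training pairs.
#' @param batch_size Batch size.
#' @param drop_last Drop the trailing incomplete batch (default `TRUE`).
#' @param epochs Number of epochs.
#' @return Integer iteration count.
#' @export
iterations_per_epoch <- function(n_pairs, batch_size, drop_last = TRUE) {
  if (drop_last) as.integer(n_pairs %/% batch_size)
  else as.integer(ceiling(n_pairs / batch_size))
}

#' @rdname iterations_per_epoch
#' @export
cumulative_iterations <- function(epochs, n_pairs, batch_size, drop_last = TRUE) {
  as.integer(epochs) * iterations_per_epoch(n_pairs, batch_size, drop_last)
}

#' Build the conditional generator / discriminator networks
#'
#' `build_generator()` returns a pure function object: identical (noise,
#' statistics, parameters) always give the identical output, a matrix of
#' shape `output_shape` with entries in `[0, 1]` (denormalized to column
#' units by [generate_table()]). `build_discriminator()` maps a flattened
#' normalized table plus statistics to a probability strictly inside (0, 1).
#'
#' @param config A [generator_config()] / [discriminator_config()].
#' @param seed Seed for weight initialization.
#' @return A list of class `"gan_generator"` / `"gan_discriminator"` wrapping
#'   the dense network.
#' @export
build_generator <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  net <- dense_net(input_dim = config$noise_dim + config$stat_dim,
                   widths = config$layer_widths,
                   output_dim = prod(config$output_shape),
                   inject_dim = config$stat_dim,
                   inject_after = config$reinjection_layer,
                   hidden_act = "lrelu", out_act = "sigmoid", seed = seed)
  structure(list(net = net, config = config), class = "gan_generator")
}

#' @rdname build_generator
#' @param input_shape `(n_rows, n_cols)` of the tables the discriminator sees.
#' @param stat_dim Length of the conditioning statistics vector.
#' @export
build_discriminator <- function(config, input_shape = c(766L, 9L),
                                stat_dim, seed = 2L) {
  stopifnot(inherits(config, "discriminator_config"), stat_dim >= 1L)
  net <- dense_net(input_dim = prod(input_shape),
                   widths = config$layer_widths, output_dim = 1L,
                   inject_dim = as.integer(stat_dim),
                   inject_after = config$stat_injection_layer,
                   hidden_act = "lrelu", out_act = "sigmoid", seed = seed)
  structure(list(net = net, config = config,
                 input_shape = as.integer(input_shape),
                 stat_dim = as.integer(stat_dim)),
            class = "gan_discriminator")
}

# Forward passes. noise: m x noise_dim; stats_norm: m x stat_dim (normalized).
generator_forward <- function(generator, noise, stats_norm) {
  if (ncol(stats_norm) != generator$config$stat_dim)
    stop("statistics width ", ncol(stats_norm), " does not match stat_dim ",
         generator$config$stat_dim, call. = FALSE)
  net_forward(generator$net, cbind(noise, stats_norm), inject = stats_norm)
}

discriminator_forward <- function(discriminator, tables_flat, stats_norm) {
  if (ncol(tables_flat) != prod(discriminator$input_shape))
    stop("table width does not match discriminator input shape", call. = FALSE)
  net_forward(discriminator$net, tables_flat, inject = stats_norm)
}

clamp_scores <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Adversarial losses
#'
#' `discriminator_loss()` is the negated ascent objective,
#' `-(1/m) sum(log D(x) + log(1 - D(G(z))))`, minimized by the discriminator.
#' `generator_loss()` is `(1/m) sum(log(1 - D(G(z)))) + ts`, the minimax
#' generator term plus the table-similarity penalty. Scores at exactly 0 or 1
#' are clamped by 1e-7 to keep the logs finite.
#'
#' @param real_scores,fake_scores Probability vectors in (0, 1).
#' @param ts Non-negative table-similarity batch loss.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(real_scores, fake_scores) {
  r <- clamp_scores(real_scores); f <- clamp_scores(fake_scores)
  -(mean(log(r)) + mean(log(1 - f)))
}

#' @rdname discriminator_loss
#' @export
generator_loss <- function(fake_scores, ts = 0) {
  stopifnot(ts >= 0)
  f <- clamp_scores(fake_scores)
  mean(log(1 - f)) + ts
}

# Normalize a table to [0,1] by schema column ranges; flat vectors are
# column-major. Degenerate ranges map to 0.
normalize_table <- function(values, schema) {
  out <- values
  for (cs in schema$columns) {
    rng <- cs$max_value - cs$min_value
    out[, cs$name] <- if (rng <= 0) 0 else (values[, cs$name] - cs$min_value) / rng
  }
  out
}

denormalize_table <- function(values01, schema) {
  cols <- schema_columns(schema)
  out <- values01
  for (k in seq_along(cols)) {
    cs <- schema$columns[[k]]
    out[, k] <- values01[, k] * (cs$max_value - cs$min_value) + cs$min_value
  }
  colnames(out) <- cols
  out
}

#' Fit the statistics-conditioned GAN
#'
#' Trains the conditional generator/discriminator pair on a
#' [build_training_corpus()] of paired (statistics vector, table) samples.
#' Each iteration draws a mini-batch of pairs, updates the discriminator on
#' real tables vs freshly generated ones (both conditioned on the matching
#' statistics), then updates the generator on the adversarial term plus the
#' table-similarity batch loss against the paired real tables. Tables are
#' compared and discriminated in normalized `[0, 1]` column units. The
#' repeated-minimum fraction of the TS loss is piecewise constant and is
#' treated as a per-evaluation constant during backpropagation.
#'
#' @param corpus A `training_corpus`.
#' @param generator A [generator_config()]; `NULL` builds the default for the
#'   corpus shape.
#' @param discriminator A [discriminator_config()].
#' @param control A [train_config()].
#' @return An object of class `"tsgan"` with components `generator`,
#'   `discriminator`, `schema`, `history` (one row per iteration: losses and
#'   TS component), `scatter` (per-epoch snapshot of the monitored feature
#'   pair), and the three configs. Methods: `print`, `summary`, `plot`,
#'   `coef`, `predict`, `simulate`.
#' @seealso [generate_table()] to sample tables from the fit.
#' @export
tsgan <- function(corpus, generator = NULL,
                  discriminator = discriminator_config(),
                  control = train_config()) {
  stopifnot(inherits(corpus, "training_corpus"))
  schema <- corpus$schema
  n_cols <- length(schema_columns(schema))
  n_rows <- corpus$n_rows
  stat_dim <- length(stat_names(schema))
  if (is.null(generator))
    generator <- generator_config(stat_dim = stat_dim,
                                  output_shape = c(n_rows, n_cols))
  stopifnot(inherits(generator, "generator_config"),
            inherits(discriminator, "discriminator_config"),
            inherits(control, "train_config"))
  if (generator$stat_dim != stat_dim)
    stop("generator stat_dim (", generator$stat_dim,
         ") does not match the corpus statistics width (", stat_dim, ")",
         call. = FALSE)
  if (!all(generator$output_shape == c(n_rows, n_cols)))
    stop("generator output_shape does not match the corpus tables", call. = FALSE)

  # load and normalize the whole corpus (column-major flat rows)
  tables_flat <- t(vapply(corpus$table_paths, function(p) {
    tb <- read_table_csv(p, schema)
    as.vector(normalize_table(unclass(tb), schema))
  }, numeric(n_rows * n_cols)))
  stats_norm <- t(vapply(corpus$stats, normalize_statistics,
                         numeric(stat_dim), schema = schema))

  gen <- build_generator(generator, seed = derive_seed(control$seed, "gen-init"))
  disc <- build_discriminator(discriminator, input_shape = c(n_rows, n_cols),
                              stat_dim = stat_dim,
                              seed = derive_seed(control$seed, "disc-init"))
  g_state <- adam_init(gen$net)
  d_state <- adam_init(disc$net)

  b <- control$batch_size
  ipe <- iterations_per_epoch(corpus$n_tables, b, control$drop_last_batch)
  if (ipe < 1L) stop("batch size exceeds the corpus size", call. = FALSE)
  total_iter <- control$max_epochs * ipe
  hist <- data.frame(iteration = seq_len(total_iter),
                     epoch = rep(seq_len(control$max_epochs), each = ipe),
                     d_loss = NA_real_, g_adv = NA_real_, ts = NA_real_,
                     g_loss = NA_real_)
  scatter <- vector("list", control$max_epochs)
  mp <- control$monitor_feature_pair

  with_seed(control$seed, {
    it <- 0L
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(corpus$n_tables)
      last_fake <- NULL
      for (k in seq_len(ipe)) {
        idx <- ord[((k - 1L) * b + 1L):(k * b)]
        sb <- stats_norm[idx, , drop = FALSE]
        rb <- tables_flat[idx, , drop = FALSE]
        m <- length(idx)

        ## --- discriminator update ---
        noise <- matrix(stats::rnorm(m * generator$noise_dim), m)
        fk <- generator_forward(gen, noise, sb)
        dr <- discriminator_forward(disc, rb, sb)
        df <- discriminator_forward(disc, fk$out, sb)
        p_r <- clamp_scores(dr$out); p_f <- clamp_scores(df$out)
        d_loss <- -(mean(log(p_r)) + mean(log(1 - p_f)))
        bw_r <- net_backward(disc$net, dr$cache, (p_r - 1) / m)
        bw_f <- net_backward(disc$net, df$cache, p_f / m)
        d_grads <- mapply(function(gr, gf)
          list(W = gr$W + gf$W, b = gr$b + gf$b),
          bw_r$grads, bw_f$grads, SIMPLIFY = FALSE)
        upd <- adam_step(disc$net, d_grads, d_state,
                         control$lr_discriminator, t = it + 1L,
                         beta1 = control$adam_beta1, beta2 = control$adam_beta2)
        disc$net <- upd$net; d_state <- upd$state

        ## --- generator update ---
        noise <- matrix(stats::rnorm(m * generator$noise_dim), m)
        fk <- generator_forward(gen, noise, sb)
        df <- discriminator_forward(disc, fk$out, sb)
        p_f <- clamp_scores(df$out)
        g_adv <- mean(log(1 - p_f))
        # adversarial gradient w.r.t. the fake tables, through the discriminator
        bw <- net_backward(disc$net, df$cache, -p_f / m)
        dX <- bw$dX
        # TS loss and gradient per pair (normalized units)
        Ls <- numeric(m)
        ts_grads <- matrix(0, m, n_rows * n_cols)
        for (j in seq_len(m)) {
          sg <- ts_sample_gradient(matrix(rb[j, ], n_rows, n_cols),
                                   matrix(fk$out[j, ], n_rows, n_cols))
          Ls[j] <- sg$L
          ts_grads[j, ] <- as.vector(sg$grad)
        }
        lts <- sqrt(mean(Ls))
        if (lts > 0) dX <- dX + ts_grads / (2 * m * lts)
        dZ <- dX * fk$out * (1 - fk$out)  # through the output sigmoid
        bwg <- net_backward(gen$net, fk$cache, dZ)
        upd <- adam_step(gen$net, bwg$grads, g_state,
                         control$lr_generator, t = it + 1L,
                         beta1 = control$adam_beta1, beta2 = control$adam_beta2)
        gen$net <- upd$net; g_state <- upd$state

        it <- it + 1L
        hist$d_loss[it] <- d_loss
        hist$g_adv[it] <- g_adv
        hist$ts[it] <- lts
        hist$g_loss[it] <- g_adv + lts
        if (!all(is.finite(c(d_loss, g_adv, lts))))
          stop("non-finite loss at iteration ", it,
               " (d_loss = ", d_loss, ", g_adv = ", g_adv, ", ts = ", lts, ")",
               call. = FALSE)
        last_fake <- fk$out[1L, ]
      }
      fake_mat <- denormalize_table(matrix(last_fake, n_rows, n_cols), schema)
      scatter[[epoch]] <- fake_mat[, mp, drop = FALSE]
      if (control$verbose)
        message(sprintf("epoch %3d/%d  d=%.4f g=%.4f ts=%.4f",
                        epoch, control$max_epochs, d_loss, g_adv, lts))
    }
  })

  structure(list(generator = gen, discriminator = disc, schema = schema,
                 generator_config = generator,
                 discriminator_config = discriminator, control = control,
                 history = hist, scatter = scatter,
                 stat_dim = stat_dim, n_iterations = total_iter,
                 iterations_per_epoch = ipe,
                 example_stats = corpus$stats[[1L]]),
            class = "tsgan")
}

#' Generate a table from a fitted or freshly built generator
#'
#' One forward pass with fresh seeded noise, conditioned on the given
#' statistics vector, then denormalized to column units. Post-processing
#' (default) clips every cell to its column range, rounds count columns,
#' thresholds the outcome column at 0.5 and guarantees both outcome classes
#' appear (flipping the single most borderline row if needed).
#'
#' @param generator A fitted `"tsgan"` object or a `"gan_generator"`.
#' @param stats A valid `stats_vector` for `schema`.
#' @param schema Table schema (defaults to the one carried by `stats`).
#' @param seed Integer seed for the noise draw.
#' @param postprocess Apply the cleanup above (default `TRUE`). When `FALSE`
#'   the raw denormalized matrix is returned.
#' @return A [new_table()] (or plain matrix when `postprocess = FALSE`).
#' @export
generate_table <- function(generator, stats, schema = attr(stats, "schema"),
                           seed = 1L, postprocess = TRUE) {
  gen <- if (inherits(generator, "tsgan")) generator$generator else generator
  stopifnot(inherits(gen, "gan_generator"))
  viol <- validate_statistics(stats, schema)
  if (length(viol))
    stop("invalid statistics: ", paste(viol, collapse = "; "), call. = FALSE)
  cfg <- gen$config
  sv <- matrix(normalize_statistics(stats, schema), nrow = 1L)
  noise <- with_seed(seed, matrix(stats::rnorm(cfg$noise_dim), nrow = 1L))
  out01 <- generator_forward(gen, noise, sv)$out
  m01 <- matrix(out01[1L, ], cfg$output_shape[1L], cfg$output_shape[2L])
  vals <- denormalize_table(m01, schema)
  if (!postprocess) return(vals)
  oc <- outcome_column(schema)
  for (cs in schema$columns) {
    v <- pmin(pmax(vals[, cs$name], cs$min_value), cs$max_value)
    if (cs$kind == "count") v <- round(v)
    vals[, cs$name] <- v
  }
  raw <- vals[, oc]
  y <- as.numeric(raw > 0.5)
  if (all(y == 0)) y[which.max(raw)] <- 1
  if (all(y == 1)) y[which.min(raw)] <- 0
  vals[, oc] <- y
  new_table(vals, schema)
}

#' @export
print.tsgan <- function(x, ...) {
  cat("Statistics-conditioned GAN fit\n")
  cat(sprintf("  corpus: %d iterations (%d epochs x %d/epoch), batch %d\n",
              x$n_iterations, x$control$max_epochs, x$iterations_per_epoch,
              x$control$batch_size))
  cat(sprintf("  output: %d x %d tables, %d conditioning statistics\n",
              x$generator_config$output_shape[1L],
              x$generator_config$output_shape[2L], x$stat_dim))
  last <- x$history[x$n_iterations, ]
  cat(sprintf("  final losses: discriminator %.4f, generator %.4f (TS %.4f)\n",
              last$d_loss, last$g_loss, last$ts))
  invisible(x)
}

#' @export
summary.tsgan <- function(object, ...) {
  h <- object$history
  ipe <- object$iterations_per_epoch
  first <- h[h$epoch == 1L, ]
  last <- h[h$epoch == max(h$epoch), ]
  out <- list(
    epochs = object$control$max_epochs,
    iterations = object$n_iterations,
    ts_first_epoch = stats::median(first$ts),
    ts_last_epoch = stats::median(last$ts),
    d_loss_last_epoch = stats::median(last$d_loss),
    g_loss_last_epoch = stats::median(last$g_loss))
  class(out) <- "summary.tsgan"
  out
}

#' @export
print.summary.tsgan <- function(x, ...) {
  cat("tsgan training summary\n")
  cat(sprintf("  %d epochs, %d iterations\n", x$epochs, x$iterations))
  cat(sprintf("  median TS loss: %.4f (first epoch) -> %.4f (last epoch)\n",
              x$ts_first_epoch, x$ts_last_epoch))
  cat(sprintf("  last-epoch median losses: discriminator %.4f, generator %.4f\n",
              x$d_loss_last_epoch, x$g_loss_last_epoch))
  invisible(x)
}

#' @export
coef.tsgan <- function(object, ...) object$generator$net$params

#' Plot training diagnostics of a fitted GAN
#'
#' `which = "loss"` draws the per-iteration discriminator/generator losses
#' and the TS component; `which = "scatter"` draws the per-epoch snapshot of
#' the monitored feature pair for a chosen epoch.
#'
#' @param x A `"tsgan"` fit.
#' @param which `"loss"` or `"scatter"`.
#' @param epoch Epoch to show when `which = "scatter"` (default: last).
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.tsgan <- function(x, which = c("loss", "scatter"),
                       epoch = x$control$max_epochs, ...) {
  which <- match.arg(which)
  h <- x$history
  if (which == "loss") {
    ylim <- range(c(h$d_loss, h$g_loss, h$ts), finite = TRUE)
    graphics::plot(h$iteration, h$d_loss, type = "l", col = "steelblue",
                   xlab = "iteration", ylab = "loss", ylim = ylim, ...)
    graphics::lines(h$iteration, h$g_loss, col = "firebrick")
    graphics::lines(h$iteration, h$ts, col = "darkgreen", lty = 2)
    graphics::legend("topright", c("discriminator", "generator", "TS"),
                     col = c("steelblue", "firebrick", "darkgreen"),
                     lty = c(1, 1, 2), bty = "n")
  } else {
    sc <- x$scatter[[epoch]]
    graphics::plot(sc[, 1L], sc[, 2L],
                   xlab = colnames(sc)[1L], ylab = colnames(sc)[2L],
                   main = sprintf("generated feature pair, epoch %d", epoch),
                   pch = 16, cex = 0.5, ...)
  }
  invisible(x)
}

#' @export
predict.tsgan <- function(object, stats = object$example_stats,
                          seed = 1L, postprocess = TRUE, ...) {
  generate_table(object, stats, object$schema, seed = seed,
                 postprocess = postprocess)
}

#' @export
simulate.tsgan <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i)
    predict(object, seed = derive_seed(seed, paste0("sim", i)), ...))
}
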