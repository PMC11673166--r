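test_that("network configurations validate their layer indices", {
  expect_error(generator_config(stat_dim = 10, layer_widths = c(8, 8),
                                reinjection_layer = 3),
               "before the final layer")
  expect_error(discriminator_config(c(8, 8), stat_injection_layer = 3),
               "before the final layer")
  g <- generator_config(stat_dim = 10)
  expect_identical(g$noise_dim, 128L)
  expect_identical(g$reinjection_layer, 2L)
  expect_identical(g$output_shape, c(766L, 9L))
})

test_that("the generator is a pure function with [0,1] outputs of the right shape", {
  sch <- tiny_schema()
  st <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  cfg <- tiny_generator_config(sch)
  gen <- build_generator(cfg, seed = 1)
  sv <- matrix(statgan:::normalize_statistics(st, sch), 1)
  noise <- matrix(rnorm(16), 1)
  o1 <- statgan:::generator_forward(gen, noise, sv)$out
  o2 <- statgan:::generator_forward(gen, noise, sv)$out
  expect_identical(o1, o2)
  expect_identical(ncol(o1), 150L)  # 50 x 3 flattened
  expect_true(all(o1 > 0 & o1 < 1))
  # stat width mismatch is caught at call time
  expect_error(statgan:::generator_forward(gen, noise, sv[, 1:3, drop = FALSE]),
               "stat_dim")
})

test_that("the discriminator outputs probabilities and is deterministic", {
  sch <- tiny_schema()
  st <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  disc <- build_discriminator(tiny_discriminator_config(),
                              input_shape = c(50, 3),
                              stat_dim = length(st), seed = 2)
  sv <- matrix(statgan:::normalize_statistics(st, sch), 1)
  x <- matrix(runif(150), 1)
  p1 <- statgan:::discriminator_forward(disc, x, sv)$out
  p2 <- statgan:::discriminator_forward(disc, x, sv)$out
  expect_identical(p1, p2)
  expect_gt(p1[1], 0); expect_lt(p1[1], 1)
})

test_that("adversarial losses match hand arithmetic", {
  eps <- 1e-7
  expect_lt(discriminator_loss(rep(1 - eps, 4), rep(eps, 4)), 1e-5)
  expect_equal(discriminator_loss(0.5, 0.5), -(log(0.5) + log(0.5)))  # 1.3863
  set.seed(1)
  r <- runif(8, 0.1, 0.9); f <- runif(8, 0.1, 0.9)
  expect_equal(discriminator_loss(r, f),
               discriminator_loss(sample(r), sample(f)))
  expect_equal(generator_loss(0.5, ts = 0), log(0.5))  # -0.6931
  expect_equal(generator_loss(f, ts = 1.7) - generator_loss(f, ts = 0), 1.7)
  expect_lt(generator_loss(1, ts = 0), log(1e-6))  # clamped toward -infinity
  expect_error(generator_loss(0.5, ts = -1))
})

test_that("iteration arithmetic follows drop-last batching", {
  expect_identical(iterations_per_epoch(10000, 64), 156L)
  expect_identical(cumulative_iterations(70, 10000, 64), 10920L)
  expect_identical(iterations_per_epoch(10000, 64, drop_last = FALSE), 157L)
  expect_identical(cumulative_iterations(2, 200, 20), 20L)
})

test_that("a short training run records finite losses and is reproducible", {
  sch <- tiny_schema()
  base <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  dir <- withr::local_tempdir()
  corpus <- build_training_corpus(base, sch, n_tables = 40, seed = 2,
                                  out_dir = dir)
  ctl <- train_config(lr_generator = 2e-3, lr_discriminator = 1e-3,
                      batch_size = 20, max_epochs = 2, seed = 7,
                      monitor_feature_pair = c(1, 2))
  fit <- tsgan(corpus, tiny_generator_config(sch),
               tiny_discriminator_config(), ctl)
  h <- fit$history
  expect_identical(nrow(h), 4L)  # 2 epochs x floor(40/20)
  expect_true(all(is.finite(as.matrix(h[, c("d_loss", "g_adv", "ts")]))))
  expect_length(fit$scatter, 2L)
  expect_identical(dim(fit$scatter[[1]]), c(50L, 2L))

  fit2 <- tsgan(corpus, tiny_generator_config(sch),
                tiny_discriminator_config(), ctl)
  expect_identical(fit$history, fit2$history)
  t1 <- predict(fit, seed = 5)
  t2 <- predict(fit2, seed = 5)
  expect_identical(unclass(t1), unclass(t2))
})

test_that("generated tables satisfy the table invariants after postprocessing", {
  sch <- tiny_schema()
  st <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  gen <- build_generator(tiny_generator_config(sch), seed = 4)
  tb <- generate_table(gen, st, sch, seed = 11)
  expect_s3_class(tb, "synth_table")
  for (cs in sch$columns) {
    expect_gte(min(tb[, cs$name]), cs$min_value)
    expect_lte(max(tb[, cs$name]), cs$max_value)
  }
  expect_setequal(unique(tb[, "Outcome"]), c(0, 1))
  expect_identical(unclass(generate_table(gen, st, sch, seed = 11)),
                   unclass(tb))
  raw <- generate_table(gen, st, sch, seed = 11, postprocess = FALSE)
  expect_true(is.matrix(raw) && !inherits(raw, "synth_table"))
})
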