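test_that("synthesized tables hit the requested risky counts exactly", {
  sch <- tiny_schema(8L)
  base <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  tgt <- base
  tgt[["Marker__risky_fraction"]] <- 0.25
  tgt[["Marker__max"]] <- 10  # keep the risky sub-range non-empty
  tb <- synthesize_table(tgt, sch, n_rows = 8, seed = 4)
  expect_equal(sum(tb[, "Marker"] > 7), round(0.25 * 8))  # recount oracle
  expect_equal(risky_fraction(tb[, "Marker"], 7, "above"), 0.25)
})

test_that("synthesized outcome column always contains both classes", {
  sch <- tiny_schema()
  base <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  for (seed in 1:5) {
    tgt <- perturb_statistics(base, 0.05, seed = seed)
    tb <- synthesize_table(tgt, sch, n_rows = 20, seed = seed)
    expect_setequal(unique(tb[, "Outcome"]), c(0, 1))
  }
  # even an extreme prevalence target keeps one row of each class
  tgt <- base
  tgt[["Outcome__prevalence"]] <- 0.0001
  tb <- synthesize_table(tgt, sch, n_rows = 20, seed = 1)
  expect_setequal(unique(tb[, "Outcome"]), c(0, 1))
})

test_that("synthesis is deterministic and errors on infeasible means", {
  sch <- tiny_schema()
  base <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  a <- synthesize_table(base, sch, seed = 9)
  b <- synthesize_table(base, sch, seed = 9)
  expect_identical(unclass(a), unclass(b))
  bad <- base
  bad[["Marker__min"]] <- 8
  bad[["Marker__max"]] <- 9
  bad[["Marker__mean"]] <- 2  # below the min: unreachable
  expect_error(synthesize_table(bad, sch, seed = 1), "Marker")
})

test_that("round-trip: extracted statistics recover the target", {
  sch <- pima_schema()
  base <- extract_statistics(make_reference_table(sch, seed = 20), sch)
  menu <- stat_menu(sch)
  ranges <- vapply(schema_columns(sch), function(cn)
    sch$columns[[cn]]$max_value - sch$columns[[cn]]$min_value, numeric(1))
  n_rows <- 150L
  for (seed in 1:12) {
    tgt <- perturb_statistics(base, 0.05, seed = seed)
    tb <- synthesize_table(tgt, sch, n_rows = n_rows, seed = seed + 100)
    got <- extract_statistics(tb, sch)
    for (col in schema_columns(sch)) {
      expect_gte(got[[paste0(col, "__min")]], tgt[[paste0(col, "__min")]] - 1e-9)
      expect_lte(got[[paste0(col, "__max")]], tgt[[paste0(col, "__max")]] + 1e-9)
      mk <- paste0(col, "__mean")
      expect_lte(abs(got[[mk]] - tgt[[mk]]), 0.01 * ranges[[col]] + 1e-9)
      rk <- paste0(col, "__risky_fraction")
      if (rk %in% names(tgt))
        expect_lte(abs(got[[rk]] - tgt[[rk]]), 1 / n_rows + 1e-9)
    }
  }
})

test_that("the reference fixture is well-formed and reproducible", {
  sch <- pima_schema()
  tb <- make_reference_table(sch, seed = 20)
  expect_identical(dim(unclass(tb)), c(766L, 9L))
  expect_setequal(unique(tb[, "Outcome"]), c(0, 1))
  expect_true(all(tb[, "Pregnancies"] == round(tb[, "Pregnancies"])))
  tb2 <- make_reference_table(sch, seed = 20)
  expect_identical(unclass(tb), unclass(tb2))
  expect_false(identical(unclass(tb),
                         unclass(make_reference_table(sch, seed = 21))))
})

test_that("corpus building writes n pairs whose CSV rows match re-extraction", {
  sch <- tiny_schema()
  base <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  dir <- withr::local_tempdir()
  corpus <- build_training_corpus(base, sch, n_tables = 6, amplitude = 0.01,
                                  seed = 8, out_dir = dir)
  expect_length(corpus$table_paths, 6L)
  expect_true(all(file.exists(corpus$table_paths)))
  stats_rows <- read_statistics_csv(corpus$stats_path, sch)
  expect_length(stats_rows, 6L)
  for (i in seq_len(6L)) {
    tb <- read_table_csv(corpus$table_paths[i], sch)
    expect_equal(as.numeric(extract_statistics(tb, sch)),
                 as.numeric(stats_rows[[i]]), tolerance = 1e-9)
  }
  reload <- read_corpus(dir)
  expect_equal(reload$n_tables, 6L)
  expect_equal(as.numeric(reload$stats[[3]]), as.numeric(corpus$stats[[3]]),
               tolerance = 1e-9)
})

test_that("identical (base, seed) give a byte-identical corpus", {
  sch <- tiny_schema()
  base <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- build_training_corpus(base, sch, n_tables = 4, seed = 5, out_dir = d1)
  c2 <- build_training_corpus(base, sch, n_tables = 4, seed = 5, out_dir = d2)
  for (i in 1:4)
    expect_identical(readLines(c1$table_paths[i]),
                     readLines(c2$table_paths[i]))
  expect_identical(readLines(c1$stats_path), readLines(c2$stats_path))
})
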