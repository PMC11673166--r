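test_that("risky_fraction counts strict exceedances in either direction", {
  expect_equal(risky_fraction(c(80, 120, 150), 100, "above"), 2 / 3)
  expect_equal(risky_fraction(c(1, 2, 3), 5, "above"), 0)
  expect_equal(risky_fraction(c(10, 20), 5, "above"), 1)
  expect_equal(risky_fraction(c(80, 120, 150), 100, "below"), 1 / 3)
  expect_equal(risky_fraction(c(100, 100), 100, "above"), 0)  # strict
  expect_error(risky_fraction(numeric(0), 1, "above"), "non-empty")
  expect_error(risky_fraction(c(1, NA), 1, "above"), "finite")
})

test_that("odds ratio is the cross-product ratio with 0.5 correction on zeros", {
  f <- flags_from_cells(10, 10, 10, 10)
  expect_equal(compute_odds_ratio(f$risky, f$outcome), 1)
  f <- flags_from_cells(10, 5, 2, 4)
  expect_equal(compute_odds_ratio(f$risky, f$outcome), 4)
  f <- flags_from_cells(10, 0, 2, 4)
  expect_equal(compute_odds_ratio(f$risky, f$outcome),
               (10.5 * 4.5) / (0.5 * 2.5))  # = 37.8
  expect_error(compute_odds_ratio(c(1, 0), c(1)), "equal length")
})

test_that("extract_statistics covers the menu and handles edge columns", {
  sch <- table_schema(list(
    column_spec("Flat", "continuous", 0, 10,
                risky_threshold = 7, risky_direction = "above"),
    column_spec("Outcome", "binary", 0, 1, is_outcome = TRUE)
  ), n_rows_default = 4)
  tb <- new_table(cbind(Flat = rep(5, 4), Outcome = c(0, 1, 0, 1)), sch)
  st <- extract_statistics(tb, sch)
  expect_equal(st[["Flat__min"]], 5)
  expect_equal(st[["Flat__max"]], 5)
  expect_equal(st[["Flat__mean"]], 5)
  expect_equal(st[["Flat__risky_fraction"]], 0)
  expect_equal(st[["Outcome__prevalence"]], 0.5)

  # 4-row toy with 2 cells above threshold: brute-force recount
  tb2 <- new_table(cbind(Flat = c(8, 9, 1, 2), Outcome = c(1, 0, 1, 0)), sch)
  st2 <- extract_statistics(tb2, sch)
  expect_equal(st2[["Flat__risky_fraction"]],
               sum(c(8, 9, 1, 2) > 7) / 4)  # = 0.5

  # default schema menu covers min/max/mean/risky/odds-ratio per feature
  menu <- stat_menu(pima_schema())
  for (col in setdiff(schema_columns(pima_schema()), "Outcome")) {
    got <- menu$statistic[menu$column == col]
    expect_setequal(got, c("min", "max", "mean", "risky_fraction", "odds_ratio"))
  }
  expect_true("prevalence" %in% menu$statistic[menu$column == "Outcome"])
})

test_that("extract_statistics is invariant under row permutation", {
  sch <- tiny_schema()
  tb <- make_reference_table(sch, seed = 3)
  st <- extract_statistics(tb, sch)
  for (seed in 1:5) {
    perm <- with(list(), {set.seed(seed); sample.int(nrow(tb))})
    tb_p <- new_table(unclass(tb)[perm, ], sch)
    expect_identical(as.numeric(extract_statistics(tb_p, sch)),
                     as.numeric(st))
  }
})

test_that("perturbation stays in the amplitude envelope and repairs invariants", {
  sch <- tiny_schema()
  st <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  p <- perturb_statistics(st, amplitude = 0.01, seed = 11)
  rel <- abs(as.numeric(p) / as.numeric(st) - 1)
  rel <- rel[is.finite(rel)]  # zero-valued statistics stay zero
  expect_true(all(rel <= 0.01 + 1e-12))
  expect_length(validate_statistics(p, sch), 0L)

  expect_identical(as.numeric(perturb_statistics(st, 0, seed = 1)),
                   as.numeric(st))
  expect_identical(as.numeric(perturb_statistics(st, 0.01, seed = 5)),
                   as.numeric(perturb_statistics(st, 0.01, seed = 5)))
  # a value of 100 perturbed by 1% lands in [99, 101]
  st2 <- st
  st2[["Score__max"]] <- 100
  p2 <- perturb_statistics(st2, 0.01, seed = 2)
  expect_gte(p2[["Score__max"]], 99)
  expect_lte(p2[["Score__max"]], 101)
})

test_that("validate_statistics reports violations instead of raising", {
  sch <- tiny_schema()
  st <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  expect_length(validate_statistics(st, sch), 0L)
  bad <- st
  bad[["Marker__mean"]] <- bad[["Marker__max"]] + 1
  v <- validate_statistics(bad, sch)
  expect_length(v, 1L)
  expect_match(v, "Marker")
  bad2 <- st
  bad2[["Score__risky_fraction"]] <- 1.2
  expect_match(validate_statistics(bad2, sch), "outside \\[0, 1\\]")
})

test_that("statistics vectors round-trip through CSV at 10 significant digits", {
  sch <- tiny_schema()
  st <- extract_statistics(make_reference_table(sch, seed = 3), sch)
  st[["Marker__mean"]] <- pi  # irrational value stresses the precision
  path <- withr::local_tempfile(fileext = ".csv")
  write_statistics_csv(st, path)
  back <- read_statistics_csv(path, sch)[[1L]]
  expect_equal(as.numeric(back), as.numeric(st), tolerance = 1e-10)
  expect_identical(names(back), names(st))
})
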