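test_that("Welch t machinery matches hand evaluation and stats::t.test", {
  expect_equal(welch_t_pvalue(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t_pvalue(c(5, 5, 5), c(5, 5))$p_value, 1)
  r <- welch_t_pvalue(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1 / sqrt(2 / 3), tolerance = 1e-6)  # -1.2247
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-abs(r$statistic), 4), tolerance = 1e-9)
  expect_equal(round(r$p_value, 3), 0.288)
  # sign symmetry
  s <- welch_t_pvalue(c(2, 3, 4), c(1, 2, 3))
  expect_equal(s$statistic, -r$statistic)
  expect_equal(s$p_value, r$p_value)
  # independent oracle across random samples
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(20 + i); y <- rnorm(15, mean = 0.3)
    got <- welch_t_pvalue(x, y)
    ref <- t.test(x, y)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(welch_t_pvalue(1, c(1, 2)), "at least 2")
})

test_that("chi-square comparison uses real counts as the reference cells", {
  expect_equal(chi_square_pvalue(c(50, 50), c(50, 50))$statistic, 0)
  expect_equal(chi_square_pvalue(c(50, 50), c(50, 50))$p_value, 1)
  r <- chi_square_pvalue(c(400, 366), c(380, 386))
  expect_equal(r$statistic, 400 / 400 + 400 / 366)  # ~2.093
  expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE))
  # doubling both vectors doubles the statistic: sum((2S-2R)^2/(2R)) = 2*chi2
  expect_equal(chi_square_pvalue(2 * c(400, 366), 2 * c(380, 386))$statistic,
               2 * r$statistic)
  expect_error(chi_square_pvalue(c(0, 10), c(5, 5)), "zero real count")
})

test_that("Wasserstein distance integrates the CDF gap", {
  expect_equal(wasserstein_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_distance(0, 1, normalize = FALSE), 1)
  expect_equal(wasserstein_distance(c(0, 1), c(0.5, 1), normalize = FALSE),
               0.25)
  # equal-size samples: mean absolute difference of sorted values
  set.seed(9)
  for (i in 1:8) {
    x <- runif(30); y <- runif(30)
    expect_equal(wasserstein_distance(x, y, normalize = FALSE),
                 mean(abs(sort(x) - sort(y))), tolerance = 1e-12)
  }
  # translation detection: shifting one sample by c adds exactly |c|
  x <- runif(25)
  expect_equal(wasserstein_distance(x, x + 0.3, normalize = FALSE), 0.3,
               tolerance = 1e-12)
  # unequal sizes against a fine-grid numeric oracle
  x <- c(0, 0.2, 0.9); y <- c(0.1, 0.4, 0.5, 1)
  grid <- seq(-0.5, 1.5, by = 1e-4)
  oracle <- sum(abs(ecdf(x)(grid) - ecdf(y)(grid))) * 1e-4
  expect_equal(wasserstein_distance(x, y, normalize = FALSE), oracle,
               tolerance = 1e-3)
  expect_error(wasserstein_distance(c(1, 1), c(0, 2)), "degenerate")
})

test_that("pass counts map to verbal labels with the zero and majority rules", {
  expect_identical(label_from_counts(7, 8), "Excellent")
  expect_identical(label_from_counts(2, 8), "Good")
  expect_identical(label_from_counts(0, 8), "Poor")
  expect_identical(label_from_counts(4, 8), "Good")  # exactly half: conservative
  expect_identical(label_from_counts(5, 8), "Excellent")
  expect_identical(label_from_counts(1, 1), "Excellent")
})

test_that("resemblance aggregation matches brute-force enumeration", {
  expect_identical(ura_total(c("Good", "Excellent", "Good")), "Good")
  expect_identical(ura_total(c("Excellent", "Excellent", "Excellent")),
                   "Excellent")
  expect_identical(ura_total(c("Good", "Excellent", "Excellent")), "Excellent")
  expect_error(ura_total(c("Good", "Superb")), "unknown label")

  # brute force over all 27 combinations, independent implementation
  lvls <- c("Poor", "Good", "Excellent")
  combos <- expand.grid(a = lvls, b = lvls, c = lvls,
                        stringsAsFactors = FALSE)
  brute <- function(l) {
    num <- match(l, lvls)            # Poor=1, Good=2, Excellent=3
    total <- sum(num * (1 / 3))
    lvls[max(1, min(3, floor(total + 0.5)))]
  }
  for (i in seq_len(nrow(combos))) {
    l <- unlist(combos[i, ])
    expect_identical(ura_total(l), brute(l))
  }
  # the display-rounded coefficient 0.33 reproduces the same totals
  for (i in seq_len(nrow(combos))) {
    l <- unlist(combos[i, ])
    expect_identical(ura_total(l, coefficient = 0.33), ura_total(l))
  }
})

test_that("fidelity_report agrees with per-column recomputation", {
  sch <- pima_schema()
  real <- make_reference_table(sch, seed = 20)
  # self-comparison: everything passes
  self <- fidelity_report(real, real, sch)
  expect_true(all(self$results$passes))
  expect_true(all(self$labels == "Excellent"))
  expect_identical(self$ura, "Excellent")
  expect_equal(self$coefficient, 1 / 3)
  expect_identical(sprintf("%.2f", self$coefficient), "0.33")

  # noise-corrupted copy, checked against an independent per-column loop
  noisy <- unclass(real)
  set.seed(1)
  feats <- setdiff(schema_columns(sch), "Outcome")
  noisy[, feats] <- noisy[, feats] + matrix(rnorm(766 * 8, 0, 3), 766)
  for (cs in sch$columns)
    noisy[, cs$name] <- pmin(pmax(noisy[, cs$name], cs$min_value), cs$max_value)
  noisy[, "Pregnancies"] <- round(noisy[, "Pregnancies"])
  noisy[, "Outcome"] <- real[, "Outcome"]
  synth <- new_table(noisy, sch)
  rep <- fidelity_report(real, synth, sch)
  for (col in feats) {
    row_t <- rep$results[rep$results$column == col &
                         rep$results$metric == "t_test", ]
    ref_t <- t.test(real[, col], synth[, col])
    expect_equal(row_t$statistic, unname(ref_t$statistic), tolerance = 1e-9)
    expect_equal(row_t$p_value, ref_t$p.value, tolerance = 1e-9)
    expect_identical(row_t$passes, ref_t$p.value > 0.05)
    row_w <- rep$results[rep$results$column == col &
                         rep$results$metric == "wasserstein", ]
    rng <- max(real[, col]) - min(real[, col])
    expect_equal(row_w$statistic,
                 mean(abs(sort(real[, col]) - sort(synth[, col]))) / rng,
                 tolerance = 1e-9)
  }
  expect_identical(rep$ura,
                   ura_total(unname(rep$labels)))
})
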