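test_that("the stratified split has exact sizes and keeps class balance", {
  sch <- pima_schema()
  real <- make_reference_table(sch, seed = 20)
  sp <- split_real(real, 0.8, seed = 42)
  expect_identical(nrow(sp$train), 612L)  # floor(0.8 * 766)
  expect_identical(nrow(sp$test), 154L)
  # partition: union restores the table, no overlap
  all_rows <- rbind(unclass(sp$train), unclass(sp$test))
  key <- function(m) sort(apply(m, 1, paste, collapse = "|"))
  expect_identical(key(all_rows), key(unclass(real)))
  # stratification: class shares close to the full table's
  p_full <- mean(real[, "Outcome"])
  expect_lte(abs(mean(sp$test[, "Outcome"]) - p_full), 1 / nrow(sp$test))
  expect_setequal(unique(sp$train[, "Outcome"]), c(0, 1))
  expect_setequal(unique(sp$test[, "Outcome"]), c(0, 1))

  tiny <- tiny_schema(4L)
  tb <- new_table(cbind(Marker = 1:4, Score = 1:4,
                        Outcome = c(1, 0, 0, 0)), tiny)
  expect_error(split_real(tb, 0.5, 1), "at least 2 rows")
})

test_that("the four model specifications carry the fixed hyperparameters", {
  specs <- default_model_specs()
  kinds <- vapply(specs, `[[`, character(1), "kind")
  expect_identical(kinds, c("random_forest", "knn", "decision_tree", "mlp"))
  rf <- specs[[1]]
  expect_identical(rf$hyperparameters$n_estimators, 88L)
  expect_identical(rf$hyperparameters$max_depth, 11L)
  expect_identical(rf$hyperparameters$criterion, "gini")
  expect_identical(rf$random_state, 28L)
  knn <- specs[[2]]
  expect_identical(knn$hyperparameters$n_neighbors, 4L)
  expect_identical(knn$hyperparameters$metric, "cosine")
  dt <- specs[[3]]
  expect_identical(dt$hyperparameters$max_depth, 7L)
  expect_identical(dt$hyperparameters$max_features, 2L)
  expect_identical(dt$random_state, 27L)
  mlp <- specs[[4]]
  expect_identical(mlp$hyperparameters$hidden_layer_sizes, c(32L, 128L, 256L))
  expect_identical(mlp$hyperparameters$max_iter, 30L)
  expect_identical(mlp$random_state, 9L)
  expect_equal(mlp$hyperparameters$early_stop_tol, 1e-4)
  expect_identical(mlp$hyperparameters$early_stop_patience, 10L)
})

test_that("cosine KNN votes deterministically among nearest neighbours", {
  knn <- statgan:::knn_cosine_predict
  # four train points along two directions; cosine ignores magnitude
  Xtr <- rbind(c(1, 0), c(2, 0), c(4, 0), c(0, 1))
  ytr <- c(1, 1, 1, 0)
  expect_identical(knn(Xtr, ytr, rbind(c(10, 0)), k = 3), 1)
  expect_identical(knn(Xtr, ytr, rbind(c(0, 5)), k = 1), 0)
  # tie at k = 2 resolves to the single nearest neighbour's class
  Xtr2 <- rbind(c(1, 0), c(0, 1))
  expect_identical(knn(Xtr2, c(1, 0), rbind(c(1, 0.1)), k = 2), 1)
})

test_that("metrics are coherent with a confusion-matrix recomputation", {
  sch <- pima_schema()
  real <- make_reference_table(sch, seed = 20)
  synth <- synthesize_table(extract_statistics(real, sch), sch, seed = 31)
  rep <- run_tstr_trtr(real, synth, split_seed = 42)
  m <- as.matrix(rep$results[, c("accuracy", "precision", "recall", "f1")])
  expect_true(all(m >= 0 & m <= 1))
  for (kind in names(rep$predictions)) {
    p <- rep$predictions[[kind]]
    for (proto in c("trtr", "tstr")) {
      pred <- p[[proto]]
      cm <- table(factor(p$truth, c(0, 1)), factor(pred, c(0, 1)))
      acc <- sum(diag(cm)) / sum(cm)
      row <- rep$results[rep$results$model == kind &
                         rep$results$protocol == toupper(proto), ]
      expect_equal(row$accuracy, acc, tolerance = 1e-12)
      # weighted recall equals accuracy for these label sets
      expect_equal(row$recall, acc, tolerance = 1e-12)
    }
  }
  expect_equal(rep$differences$accuracy,
               abs(m[seq(1, 7, 2), "accuracy"] - m[seq(2, 8, 2), "accuracy"]),
               ignore_attr = TRUE)
})

test_that("utility labels follow the strict 0.4 rule", {
  mk <- function(d) structure(list(differences = data.frame(
    model = "m", accuracy = d, precision = d, recall = d, f1 = d)),
    class = "utility_report")
  expect_identical(utility_label(mk(0)), "Excellent")
  expect_identical(utility_label(mk(0.39)), "Excellent")
  expect_identical(utility_label(mk(0.4)), "Good")   # strict inequality
  expect_identical(utility_label(mk(0.79)), "Good")
  expect_identical(utility_label(mk(0.9)), "Poor")
  # the benchmark KNN accuracy gap (0.6623 vs 0.6494) is far below threshold
  bu <- benchmark_results("utility")
  knn <- bu[bu$model == "knn", ]
  gap <- abs(knn$accuracy[knn$method == "Real"] -
             knn$accuracy[knn$method == "Proposed"])
  expect_equal(gap, 0.0129, tolerance = 1e-9)
  expect_lt(gap, 0.4)
})
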