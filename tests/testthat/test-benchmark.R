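# Small feature table with direct control over the signal, for protocol tests.
fabricated_features <- function(n, signal = 1, seed = 1) {
  set.seed(seed)
  label <- rbinom(n, 1, 0.35)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 1] <- x[, 1] + signal * label
  x[, 5] <- x[, 5] + signal * label
  df <- as.data.frame(x)
  names(df) <- feature_names()
  df$label <- label
  df
}

test_that("AUROC equals the Mann-Whitney concordance probability", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.5, 0.5), c(1, 0)), 0.5)  # full tie = half credit
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "one class")
})

test_that("AUROC agrees exactly with all-pairs counting, ties included", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("stratified folds preserve the class ratio and are seed-deterministic", {
  labels <- c(rep(1, 5), rep(0, 5))
  f <- stratified_folds(labels, 5, seed = 3)
  for (k in 1:5) expect_equal(sum(labels[f == k]), 1)

  set.seed(5)
  labels <- rbinom(500, 1, 0.3)
  f <- stratified_folds(labels, 5, seed = 9)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 500)
  # per-fold class counts within 1 of proportionality
  for (cls in 0:1) {
    cnt <- table(f[labels == cls])
    expect_lte(max(cnt) - min(cnt), 1)
  }
  expect_identical(f, stratified_folds(labels, 5, seed = 9))
  expect_false(identical(f, stratified_folds(labels, 5, seed = 10)))
  expect_error(stratified_folds(c(1, 0, 0, 0, 0, 0), 5), "fewer")
})

test_that("class weights follow the inverse-frequency closed form", {
  labels <- c(rep(0, 150), rep(1, 50))
  wb <- class_weights(labels, "balanced")
  expect_equal(unname(wb), c(200 / 300, 200 / 100), tolerance = 1e-12)
  expect_equal(wb[["0"]] * 150, wb[["1"]] * 50)  # conservation
  wn <- class_weights(labels, "normalized")
  expect_equal(unname(wn), c(1, 3))
  # at a 1.84:1 imbalance the two weight parameterizations print as
  # 0.77/1.42 and 1.00/1.84 and are proportional
  lab2 <- c(rep(0, 184), rep(1, 100))
  expect_equal(round(unname(class_weights(lab2, "balanced")), 2), c(0.77, 1.42))
  expect_equal(round(unname(class_weights(lab2, "normalized")), 2), c(1.00, 1.84))
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("the benchmark runs all seven methods and is reproducible", {
  ft <- fabricated_features(300, signal = 2, seed = 2)
  cfg <- benchmark_config(seed = 4)
  b <- run_benchmark(ft, cfg)
  expect_s3_class(b, "ptq_benchmark")
  expect_length(b$results, 7L)
  expect_setequal(names(b$results), c("knn", "svml", "svmr", "lr", "dt", "rf", "xgb"))
  for (r in b$results) {
    expect_length(r$fold_auroc, 5L)
    expect_true(all(r$fold_auroc >= 0 & r$fold_auroc <= 1))
    expect_equal(r$mean, mean(r$fold_auroc))
    expect_equal(r$sd, sd(r$fold_auroc))
  }
  expect_false(b$results$knn$weighted)
  b2 <- run_benchmark(ft, cfg)
  expect_equal(summary(b), summary(b2))
})

test_that("strong separable signal drives every method near-perfect", {
  ft <- fabricated_features(400, signal = 8, seed = 6)
  b <- run_benchmark(ft, benchmark_config(seed = 1, rf_trees = 100L))
  for (r in b$results) expect_gte(r$mean, 0.99)
})

test_that("training-fold scaling never sees test instances", {
  x <- matrix(rnorm(200), 20, 10)
  sc <- ptqsar:::.fold_scale(x[1:15, ], x[16:20, ])
  x_outlier <- x
  x_outlier[18, ] <- 1e6  # sentinel placed only in the test split
  sc2 <- ptqsar:::.fold_scale(x_outlier[1:15, ], x_outlier[16:20, ])
  expect_identical(sc$train, sc2$train)
  expect_identical(sc$test[-3, ], sc2$test[-3, ])
})

test_that("non-finite features and degenerate inputs raise pointed errors", {
  ft <- fabricated_features(100, seed = 3)
  ft$d_theta5_seq[7] <- Inf
  expect_error(run_benchmark(ft, benchmark_config(methods = "lr")), "row 7")
  expect_error(run_benchmark(ft[0, ], benchmark_config(methods = "lr")), "empty")
})

test_that("tree scan reuses folds and covers the standard counts", {
  ft <- fabricated_features(250, signal = 1.5, seed = 8)
  ts <- rf_tree_scan(ft, tree_counts = c(1, 5), cfg = benchmark_config(seed = 2))
  expect_setequal(names(ts$results), c("rf1", "rf5"))
  expect_true(all(unlist(lapply(ts$results, `[[`, "fold_auroc")) >= 0))
  expect_true(all(unlist(lapply(ts$results, `[[`, "fold_auroc")) <= 1))
  # same folds for every count: paired comparison
  expect_identical(ts$folds, stratified_folds(ft$label, 5, 2))
  # the default grid is the standard 10-point scan
  expect_identical(eval(formals(rf_tree_scan)$tree_counts),
                   c(5, 10, 20, 30, 40, 50, 100, 200, 500, 1000))
})

test_that("feature importances are normalized per fold and complete", {
  ft <- fabricated_features(300, signal = 2, seed = 12)
  imp <- rank_feature_importance(ft, benchmark_config(rf_trees = 50L, seed = 3))
  expect_setequal(imp$feature, feature_names())
  expect_equal(nrow(imp), 10L)
  for (f in paste0("fold", 1:5)) {
    expect_true(all(imp[[f]] >= 0))
    expect_lt(abs(sum(imp[[f]]) - 1), 1e-9)
  }
  expect_false(is.unsorted(rev(imp$importance)))
  # planted signal on two columns is recovered at the top
  expect_setequal(imp$feature[1:2], c("e_ref", "d_theta5_seq"))
})

test_that("boxplot report writes a deterministic CSV twin of the plot", {
  ft <- fabricated_features(200, seed = 5)
  b <- run_benchmark(ft, benchmark_config(methods = c("lr", "dt", "rf"), seed = 6))
  prefix <- file.path(withr::local_tempdir(), "bench")
  paths <- boxplot_report(b, prefix)
  expect_true(file.exists(paste0(prefix, ".png")))
  expect_true(file.exists(paste0(prefix, ".csv")))
  got <- utils::read.csv(paste0(prefix, ".csv"))
  expect_equal(got$mean, sapply(b$results, `[[`, "mean"),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(got$mean, rowMeans(got[, paste0("fold", 1:5)]), tolerance = 1e-5)
  first <- readLines(paste0(prefix, ".csv"))
  boxplot_report(b, prefix)
  expect_identical(readLines(paste0(prefix, ".csv")), first)
})
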