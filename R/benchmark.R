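#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the fraction of
#' positive-negative pairs in which the positive scores higher, with half
#' credit for ties. Implemented through midranks, which is algebraically
#' identical to pair counting.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1), same length as `scores`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC is undefined when only one class is present", call. = FALSE)
  }
  r <- rank(scores)  # midranks give ties half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Partitions instances into `n_folds` folds preserving the class ratio:
#' within each class, a seeded permutation is dealt round-robin, so
#' per-fold class counts differ from exact proportionality by at most one.
#' Deterministic given the seed.
#'
#' @param labels binary labels (0/1).
#' @param n_folds number of folds (default 5).
#' @param seed integer RNG seed.
#' @return Integer vector of fold ids in `1..n_folds`, one per instance.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 42L) {
  labels <- as.integer(labels)
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < n_folds)) {
    stop(sprintf("class %s has fewer members (%d) than folds (%d)",
                 names(tab)[which(tab < n_folds)[1]],
                 min(tab), n_folds), call. = FALSE)
  }
  fold <- integer(length(labels))
  rng <- local_rng(seed)
  on.exit(rng())
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Save the RNG state, seed, and return a restorer.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Class weights for imbalanced binary labels
#'
#' Balanced mode weights each class inversely to its frequency,
#' `w_c = N / (2 * n_c)`, so that `w_0 * n_0 = w_1 * n_1`. Normalized mode
#' rescales the balanced weights so the majority-class weight `w_0` is 1;
#' the two modes are proportional and train identically in learners that
#' only use weight ratios.
#'
#' @param labels binary labels (0/1).
#' @param mode `"balanced"` or `"normalized"`.
#' @return Named numeric vector `c("0" = w_0, "1" = w_1)`.
#' @export
class_weights <- function(labels, mode = c("balanced", "normalized")) {
  mode <- match.arg(mode)
  labels <- as.integer(labels)
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L) {
    stop("class weights need both classes present", call. = FALSE)
  }
  n <- n0 + n1
  w <- c("0" = n / (2 * n0), "1" = n / (2 * n1))
  if (mode == "normalized") w <- w / w[["0"]]
  w
}

#' Benchmark configuration
#'
#' @param methods subset of `"knn"`, `"svml"`, `"svmr"`, `"lr"`, `"dt"`,
#'   `"rf"`, `"xgb"` (default: all seven).
#' @param n_folds stratified folds (default 5).
#' @param seed top-level RNG seed driving fold shuffling and stochastic
#'   learners (default 42).
#' @param weight_mode class-weight mode, see [class_weights()].
#' @param knn_k nearest-neighbor count (default 5).
#' @param rf_trees random-forest tree count for the method comparison
#'   (default 10).
#' @param xgb_rounds boosting rounds (default 100, the common toolkit
#'   default).
#' @param scale per-fold standardization of features fitted on the
#'   training split only (default `TRUE`).
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(methods = c("knn", "svml", "svmr", "lr", "dt", "rf", "xgb"),
                             n_folds = 5L, seed = 42L,
                             weight_mode = c("balanced", "normalized"),
                             knn_k = 5L, rf_trees = 10L, xgb_rounds = 100L,
                             scale = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  weight_mode <- match.arg(weight_mode)
  stopifnot(n_folds >= 2L, knn_k >= 1L, rf_trees >= 1L, xgb_rounds >= 1L)
  structure(list(methods = methods, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), weight_mode = weight_mode,
                 knn_k = as.integer(knn_k), rf_trees = as.integer(rf_trees),
                 xgb_rounds = as.integer(xgb_rounds), scale = scale),
            class = "benchmark_config")
}

# Standardize train/test feature matrices with statistics fitted on the
# training split only; constant columns are left centered but unscaled.
.fold_scale <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sd <- apply(xtr, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(train = sweep(sweep(xtr, 2, mu), 2, sd, "/"),
       test  = sweep(sweep(xte, 2, mu), 2, sd, "/"))
}

# Train one method on a fold and score the held-out split.
# Returns numeric scores oriented so larger = more likely class 1.
.fit_score <- function(method, xtr, ytr, xte, w, cfg, fold_seed) {
  ytr_f <- factor(ytr, levels = c(0, 1))
  w_obs <- unname(w[as.character(ytr)])
  rng <- local_rng(fold_seed)
  on.exit(rng())
  switch(method,
    knn = {
      # nearest neighbors has no class-weight mechanism; votes are unweighted
      pred <- class::knn(xtr, xte, cl = ytr_f, k = cfg$knn_k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    svml = .svm_score(xtr, ytr_f, xte, w, kernel = "linear"),
    svmr = .svm_score(xtr, ytr_f, xte, w, kernel = "radial"),
    lr = {
      df_tr <- as.data.frame(xtr); df_tr$.y <- ytr
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df_tr,
                                         family = stats::binomial(),
                                         weights = w_obs))
      unname(stats::predict(fit, newdata = as.data.frame(xte), type = "response"))
    },
    dt = {
      df_tr <- as.data.frame(xtr); df_tr$.y <- ytr_f
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class",
                          weights = w_obs)
      unname(stats::predict(fit, newdata = as.data.frame(xte))[, "1"])
    },
    rf = {
      fit <- randomForest::randomForest(x = xtr, y = ytr_f,
                                        ntree = cfg$rf_trees, classwt = w)
      unname(stats::predict(fit, newdata = xte, type = "prob")[, "1"])
    },
    xgb = {
      dtr <- xgboost::xgb.DMatrix(xtr, label = ytr)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      scale_pos_weight = unname(w[["1"]] / w[["0"]]),
                      nthread = 1),
        data = dtr, nrounds = cfg$xgb_rounds, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(xte))
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

# SVM decision values oriented toward class "1".
.svm_score <- function(xtr, ytr_f, xte, w, kernel) {
  fit <- e1071::svm(x = xtr, y = ytr_f, kernel = kernel,
                    class.weights = w, scale = FALSE)
  dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
             "decision.values")
  # column name "a/b" means positive values favor class a
  favored <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (favored == "1") as.numeric(dv) else -as.numeric(dv)
}

#' Cross-validated AUROC benchmark of weighted classifiers
#'
#' Runs the evaluation protocol: stratified k-fold splits, per-fold
#' standardization fitted on the training split only, class-weighted
#' training of each configured method (nearest neighbors carries no
#' weights and is flagged in the result), and AUROC on each held-out
#' split. Fully reproducible given the seed.
#'
#' @param features feature data.frame with the columns of
#'   [feature_names()] plus `label`.
#' @param cfg a [benchmark_config()].
#' @param folds optional precomputed fold assignment (used to pair runs
#'   across configurations); defaults to fresh stratified folds.
#' @return An object of class `ptq_benchmark`: a list with `results` (per
#'   method: fold AUROCs, mean, sd), `folds`, `weights`, and `config`.
#' @export
run_benchmark <- function(features, cfg = benchmark_config(), folds = NULL) {
  stopifnot(inherits(cfg, "benchmark_config"))
  x <- .feature_matrix(features)
  y <- features$label
  if (is.null(folds)) folds <- stratified_folds(y, cfg$n_folds, cfg$seed)
  w <- class_weights(y, cfg$weight_mode)
  results <- lapply(seq_along(cfg$methods), function(mi) {
    method <- cfg$methods[mi]
    fold_auc <- vapply(seq_len(cfg$n_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L) {
        stop("degenerate fold (single class); check stratification", call. = FALSE)
      }
      sc <- if (cfg$scale) .fold_scale(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
            else list(train = x[tr, , drop = FALSE], test = x[!tr, , drop = FALSE])
      scores <- .fit_score(method, sc$train, y[tr], sc$test, w, cfg,
                           fold_seed = cfg$seed + 97L * f + 1009L * mi)
      auroc(scores, y[!tr])
    }, numeric(1))
    list(method = method, fold_auroc = fold_auc,
         mean = mean(fold_auc), sd = stats::sd(fold_auc),
         weighted = method != "knn")
  })
  names(results) <- cfg$methods
  structure(list(results = results, folds = folds, weights = w, config = cfg),
            class = "ptq_benchmark")
}

.feature_matrix <- function(features) {
  missing <- setdiff(c(FEATURE_COLUMNS, "label"), names(features))
  if (length(missing) > 0L) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(features) == 0L) stop("feature table is empty", call. = FALSE)
  x <- as.matrix(features[, FEATURE_COLUMNS])
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite feature value at row %d (%s)",
                 bad[1, 1], FEATURE_COLUMNS[bad[1, 2]]), call. = FALSE)
  }
  x
}

#' @export
print.ptq_benchmark <- function(x, ...) {
  cat(sprintf("Stratified %d-fold AUROC benchmark (seed %d, %s class weights)\n",
              x$config$n_folds, x$config$seed, x$config$weight_mode))
  cat(sprintf("class weights: 0: %.2f, 1: %.2f\n",
              x$weights[["0"]], x$weights[["1"]]))
  print(summary(x), row.names = FALSE, digits = 4)
  if ("knn" %in% names(x$results)) {
    cat("note: knn voting is unweighted (no class-weight mechanism)\n")
  }
  invisible(x)
}

#' @export
summary.ptq_benchmark <- function(object, ...) {
  do.call(rbind, lapply(object$results, function(r) {
    data.frame(method = r$method,
               t(matrix(r$fold_auroc,
                        dimnames = list(paste0("fold", seq_along(r$fold_auroc)), NULL))),
               mean = r$mean, sd = r$sd, row.names = NULL)
  }))
}

#' @export
plot.ptq_benchmark <- function(x, main = "AUROC by method (per-fold)", ...) {
  vals <- lapply(x$results, function(r) r$fold_auroc)
  graphics::boxplot(vals, ylab = "AUROC", main = main, ...)
  invisible(x)
}

#' Random-forest tree-count scan
#'
#' Re-runs the cross-validated benchmark with a random forest at each tree
#' count, reusing the same stratified folds for every count so per-fold
#' differences are paired.
#'
#' @param features feature data.frame.
#' @param tree_counts integer vector of forest sizes (default: the
#'   standard scan 5, 10, 20, 30, 40, 50, 100, 200, 500, 1000).
#' @param cfg a [benchmark_config()]; its `methods` entry is ignored.
#' @return A `ptq_benchmark` whose result names are `rf<n>`.
#' @export
rf_tree_scan <- function(features,
                         tree_counts = c(5, 10, 20, 30, 40, 50, 100, 200, 500, 1000),
                         cfg = benchmark_config()) {
  stopifnot(length(tree_counts) > 0L, all(tree_counts >= 1))
  folds <- stratified_folds(features$label, cfg$n_folds, cfg$seed)
  runs <- lapply(tree_counts, function(nt) {
    cfg_nt <- cfg
    cfg_nt$methods <- "rf"
    cfg_nt$rf_trees <- as.integer(nt)
    run_benchmark(features, cfg_nt, folds = folds)
  })
  results <- lapply(seq_along(tree_counts), function(i) {
    r <- runs[[i]]$results$rf
    r$method <- sprintf("rf%d", tree_counts[i])
    r$trees <- as.integer(tree_counts[i])
    r
  })
  names(results) <- vapply(results, `[[`, character(1), "method")
  structure(list(results = results, folds = folds,
                 weights = runs[[1]]$weights, config = cfg),
            class = "ptq_benchmark")
}

#' Cross-validated random-forest feature importance
#'
#' Fits a class-weighted random forest on each training fold (features
#' standardized per fold), normalizes the impurity-decrease importances to
#' sum to one within each fold, and averages across folds.
#'
#' @param features feature data.frame.
#' @param cfg a [benchmark_config()]; `rf_trees` sets the forest size
#'   (100 is the usual choice for a final model).
#' @return An object of class `ptq_importance`: data.frame of feature,
#'   mean importance and per-fold importances, sorted descending.
#' @export
rank_feature_importance <- function(features, cfg = benchmark_config(rf_trees = 100L)) {
  x <- .feature_matrix(features)
  y <- features$label
  folds <- stratified_folds(y, cfg$n_folds, cfg$seed)
  w <- class_weights(y, cfg$weight_mode)
  per_fold <- sapply(seq_len(cfg$n_folds), function(f) {
    tr <- folds != f
    xtr <- if (cfg$scale) .fold_scale(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])$train
           else x[tr, , drop = FALSE]
    rng <- local_rng(cfg$seed + 97L * f)
    on.exit(rng())
    fit <- randomForest::randomForest(x = xtr, y = factor(y[tr], levels = c(0, 1)),
                                      ntree = cfg$rf_trees, classwt = w,
                                      importance = FALSE)
    imp <- fit$importance[, "MeanDecreaseGini"]
    imp / sum(imp)
  })
  mean_imp <- rowMeans(per_fold)
  ord <- order(mean_imp, decreasing = TRUE)
  out <- data.frame(feature = FEATURE_COLUMNS[ord],
                    importance = unname(mean_imp[ord]),
                    per_fold[ord, , drop = FALSE], row.names = NULL)
  names(out)[-(1:2)] <- paste0("fold", seq_len(cfg$n_folds))
  structure(out, class = c("ptq_importance", "data.frame"))
}

#' @export
print.ptq_importance <- function(x, ...) {
  cat("Random-forest feature importance (impurity decrease, fold-averaged)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Box-plot report of benchmark results
#'
#' Writes a per-method box plot of fold AUROCs as PNG and a CSV twin with
#' fold values, mean, and SD (floats at 6 decimals, deterministic).
#'
#' @param bench a `ptq_benchmark`.
#' @param path output path prefix; writes `<path>.png` and `<path>.csv`.
#' @return Named character vector of the two file paths, invisibly.
#' @export
boxplot_report <- function(bench, path) {
  stopifnot(inherits(bench, "ptq_benchmark"))
  png_path <- paste0(path, ".png")
  csv_path <- paste0(path, ".csv")
  grDevices::png(png_path, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(bench)
  smry <- summary(bench)
  out <- smry
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.6f", out[[col]])
  }
  con <- file(csv_path, open = "wb")  # fixed EOL for byte-identical re-runs
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  invisible(c(png = png_path, csv = csv_path))
}
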