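#' Rank-based ROC AUC
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative (Mann-Whitney form), with tied scores counted half.
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels two-level vector; the second factor level (or `1`) is the
#'   positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train and evaluate a wild/domesticated random-forest classifier
#'
#' Randomly samples `1 - holdout_frac` of the samples (stratification-free,
#' resampling up to 10 times if a split misses a class) as the training
#' set, fits a random forest with `n_trees` trees on the OTU profiles,
#' reports AUC on the held-out fraction, `k_folds`-fold cross-validation
#' accuracy on the training set, and mean-decrease-Gini importances.
#'
#' @param table `norm_table` (samples in columns; typically CSS-log) or
#'   matrix.
#' @param labels two-level factor per sample (e.g. wild/domesticated).
#' @param holdout_frac fraction held out for the AUC estimate.
#' @param n_trees trees in the forest.
#' @param k_folds folds for the CV accuracy.
#' @param seed RNG seed.
#' @return object of class `classifier_report` with `auc`, `cv_accuracy`,
#'   `importance` (mean decrease Gini per OTU), `model`, `seed`.
#' @export
train_eval <- function(table, labels, holdout_frac = 1/3, n_trees = 1500,
                       k_folds = 10, seed = NULL) {
  X <- t(table_values(table))
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  for (attempt in 1:10) {
    train <- sort(sample.int(n, round(n * (1 - holdout_frac))))
    test <- setdiff(seq_len(n), train)
    if (nlevels(droplevels(y[train])) == 2 &&
        nlevels(droplevels(y[test])) == 2) break
    warning("single-class split; resampling (attempt ", attempt, ")")
    if (attempt == 10) stop("could not obtain a two-class split")
  }
  rf <- randomForest::randomForest(X[train, , drop = FALSE], y[train],
                                   ntree = n_trees, importance = FALSE)
  prob <- stats::predict(rf, X[test, , drop = FALSE], type = "prob")[, levels(y)[2]]
  auc <- roc_auc(prob, y[test])
  folds <- make_folds(y[train], k_folds)
  correct <- 0
  for (f in seq_along(folds)) {
    tr <- unlist(folds[-f]); te <- folds[[f]]
    m <- randomForest::randomForest(X[train, , drop = FALSE][tr, , drop = FALSE],
                                    y[train][tr], ntree = n_trees)
    pred <- stats::predict(m, X[train, , drop = FALSE][te, , drop = FALSE])
    correct <- correct + sum(pred == y[train][te])
  }
  structure(list(model_tag = "random_forest", auc = auc,
                 cv_accuracy = correct / length(train),
                 importance = sort(rf$importance[, "MeanDecreaseGini"],
                                   decreasing = TRUE),
                 model = rf, train = train, test = test, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Random-forest classifier: held-out AUC ", format(x$auc, digits = 4),
      ", CV accuracy ", format(x$cv_accuracy, digits = 4), "\n", sep = "")
  cat("Top OTUs by mean decrease in Gini:\n")
  print(utils::head(x$importance, 10), digits = 4)
  invisible(x)
}

# stratified fold assignment preserving class balance
make_folds <- function(y, k) {
  idx <- seq_along(y)
  folds <- vector("list", k)
  for (cl in levels(y)) {
    i <- sample(idx[y == cl])
    part <- split(i, rep_len(seq_len(k), length(i)))
    for (f in seq_along(part)) folds[[f]] <- c(folds[[f]], part[[f]])
  }
  folds
}

#' Cross-validated feature-elimination error curve
#'
#' For each feature count in `schedule` (decreasing), retains the top OTUs
#' by mean-decrease-Gini importance and records the `k_folds`-fold
#' cross-validation error. With `rank_mode = "per_fold"` (default) the
#' importance ranking is recomputed inside each fold from the training
#' folds only, avoiding selection leakage; `"global"` ranks once on the
#' full data. `selected_k` is the smallest count whose CV error is within
#' `tolerance` of the full-model error.
#'
#' @param table `norm_table` or matrix, samples in columns.
#' @param labels two-level factor per sample.
#' @param schedule decreasing vector of feature counts; defaults to halving
#'   from the full feature set down to 1.
#' @param k_folds CV folds.
#' @param n_trees trees per forest.
#' @param rank_mode `"per_fold"` or `"global"`.
#' @param tolerance absolute error tolerance for `selected_k`.
#' @param seed RNG seed.
#' @return object of class `feature_curve`: data.frame `curve`
#'   (`n_features`, `cv_error`) and `selected_k`.
#' @export
feature_elimination_curve <- function(table, labels, schedule = NULL,
                                      k_folds = 10, n_trees = 500,
                                      rank_mode = c("per_fold", "global"),
                                      tolerance = 0.02, seed = NULL) {
  rank_mode <- match.arg(rank_mode)
  X <- t(table_values(table))
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  p <- ncol(X)
  if (is.null(schedule)) {
    schedule <- p
    while (schedule[length(schedule)] > 1)
      schedule <- c(schedule, max(1, floor(schedule[length(schedule)] / 2)))
  }
  schedule <- sort(unique(as.integer(schedule)), decreasing = TRUE)
  if (!length(schedule)) stop("empty schedule")
  if (any(schedule < 1 | schedule > p)) stop("schedule outside [1, n_otus]")
  if (!is.null(seed)) set.seed(seed)
  folds <- make_folds(y, k_folds)
  if (rank_mode == "global") {
    rf_all <- randomForest::randomForest(X, y, ntree = n_trees)
    global_rank <- order(rf_all$importance[, "MeanDecreaseGini"],
                         decreasing = TRUE)
  }
  errs <- matrix(0, length(schedule), length(folds))
  for (f in seq_along(folds)) {
    tr <- unlist(folds[-f]); te <- folds[[f]]
    ranking <- if (rank_mode == "per_fold") {
      rf_f <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                         ntree = n_trees)
      order(rf_f$importance[, "MeanDecreaseGini"], decreasing = TRUE)
    } else global_rank
    for (s in seq_along(schedule)) {
      keep <- ranking[seq_len(schedule[s])]
      m <- randomForest::randomForest(X[tr, keep, drop = FALSE], y[tr],
                                      ntree = n_trees)
      pred <- stats::predict(m, X[te, keep, drop = FALSE])
      errs[s, f] <- sum(pred != y[te])
    }
  }
  cv_error <- rowSums(errs) / length(y)
  full_err <- cv_error[1]
  ok <- schedule[cv_error <= full_err + tolerance]
  structure(list(curve = data.frame(n_features = schedule, cv_error = cv_error),
                 selected_k = min(ok), full_error = full_err,
                 rank_mode = rank_mode, tolerance = tolerance, seed = seed),
            class = "feature_curve")
}

#' @export
print.feature_curve <- function(x, ...) {
  cat("Feature-elimination CV curve (", x$rank_mode, " ranking)\n", sep = "")
  print(x$curve, digits = 4)
  cat("selected_k =", x$selected_k, "(tolerance", x$tolerance, ")\n")
  invisible(x)
}
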