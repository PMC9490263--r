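# Train/test split, k-fold cross-validation and the classifier x
# feature-count evaluation grid, all on one fixed shuffled partition.

#' Split specification
#'
#' @param train_fraction fraction of subjects used for training
#'   (default 0.8).
#' @param seed shuffle seed.
#' @param stratified preserve class prevalence in the split
#'   (default `TRUE`).
#' @param k_folds folds for cross-validation (default 10).
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 1L, stratified = TRUE,
                       k_folds = 10) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  if (k_folds < 2) stopf("k_folds must be >= 2")
  structure(list(train_fraction = train_fraction, seed = seed,
                 stratified = stratified, k_folds = k_folds),
            class = "split_spec")
}

#' Shuffled stratified train/test split
#'
#' Test size is `floor((1 - train_fraction) * n)` built from per-class
#' floors that preserve prevalence; partitions are disjoint and
#' deterministic given the spec's seed.
#'
#' @param table a `feature_table`.
#' @param spec a [split_spec()].
#' @return list with `train`, `test` (row subsets) and `test_idx`.
#' @export
split_data <- function(table, spec = split_spec()) {
  y <- group_factor(table$group)
  if (nlevels(droplevels(y)) < 2) stopf("both classes must be present")
  test_idx <- with_seed(spec$seed, {
    if (spec$stratified) {
      unlist(lapply(levels(y), function(lv) {
        rows <- which(y == lv)
        n_test <- floor((1 - spec$train_fraction) * length(rows) + 1e-9)
        sample(rows)[seq_len(n_test)]
      }))
    } else {
      n_test <- floor((1 - spec$train_fraction) * nrow(table) + 1e-9)
      sample(nrow(table))[seq_len(n_test)]
    }
  })
  test_idx <- sort(test_idx)
  train <- table[-test_idx, , drop = FALSE]
  test <- table[test_idx, , drop = FALSE]
  if (nlevels(droplevels(group_factor(train$group))) < 2 ||
      length(unique(test$group)) < 1)
    stopf("class absent from one side of the split; n too small")
  list(train = train, test = test, test_idx = test_idx)
}

#' Evaluate a fitted classifier on held-out subjects
#'
#' Confusion-derived metrics with depression as the positive class:
#' accuracy (%), sensitivity TP/(TP+FN), specificity TN/(TN+FP). A
#' one-class test set yields NA sensitivity/specificity with a flag;
#' accuracy is still returned.
#'
#' @param model a `qeeg_classifier` (or any object with a compatible
#'   `predict` method returning the group factor).
#' @param test held-out `feature_table` rows.
#' @param positive_class positive label (default `"depression"`).
#' @return list: `accuracy` (%), `sensitivity`, `specificity`, `confusion`
#'   (TP, FP, TN, FN), `one_class` flag.
#' @export
evaluate_classifier <- function(model, test, positive_class = "depression") {
  if (!nrow(test)) stopf("empty test set")
  pred <- predict(model, test)
  truth <- as.character(test$group)
  is_pos <- truth == positive_class
  pred_pos <- as.character(pred) == positive_class
  tp <- sum(pred_pos & is_pos); fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos); fp <- sum(pred_pos & !is_pos)
  one_class <- length(unique(truth)) < 2
  list(accuracy = 100 * (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       one_class = one_class)
}

#' Stratified k-fold cross-validation loss
#'
#' Mean misclassification fraction over `k` stratified folds.
#'
#' @param train training `feature_table`.
#' @param name classifier name (see [train_classifier()]).
#' @param features feature columns or a `selected_features`.
#' @param k folds (default 10; must not exceed n).
#' @param seed fold-assignment seed.
#' @return CV loss in `[0, 1]`.
#' @export
cross_validate <- function(train, name, features, k = 10, seed = 1L) {
  n <- nrow(train)
  if (k > n) stopf("k = %d exceeds training size %d", k, n)
  y <- group_factor(train$group)
  folds <- with_seed(seed, {
    f <- integer(n)
    for (lv in levels(y)) {
      rows <- sample(which(y == lv))
      f[rows] <- rep_len(seq_len(k), length(rows))
    }
    f
  })
  losses <- vapply(seq_len(k), function(fold) {
    tr <- train[folds != fold, , drop = FALSE]
    te <- train[folds == fold, , drop = FALSE]
    if (!nrow(te)) return(NA_real_)
    model <- train_classifier(tr, name, features, seed = seed)
    mean(as.character(predict(model, te)) != as.character(te$group))
  }, 0)
  mean(losses, na.rm = TRUE)
}

#' Classifier x feature-count evaluation grid
#'
#' Evaluates every classifier at every selected feature count on the SAME
#' shuffled stratified train/test partition (no test leakage across
#' cells), with 10-fold cross-validation loss computed on the training
#' portion. The best cell maximizes test accuracy with ties broken by
#' minimum CV loss (then by grid order). Cell failures are recorded and
#' the grid completes.
#'
#' @param table full `feature_table`.
#' @param selections named list (size -> `selected_features`), e.g. from
#'   [sweep_threshold()].
#' @param classifiers classifier names (default all ten).
#' @param spec a [split_spec()].
#' @param seed base seed for classifier training and CV folds.
#' @param compute_cv compute per-cell CV loss (default `TRUE`).
#' @param split optional precomputed [split_data()] result (reused, e.g.
#'   for permutation nulls on a fixed partition).
#' @return Object of class `qeeg_report`: `grid` data.frame, `best` row,
#'   `partition` fingerprint, seeds and settings.
#' @export
run_sweep <- function(table, selections, classifiers = CLASSIFIER_NAMES,
                      spec = split_spec(), seed = 1L, compute_cv = TRUE,
                      split = NULL) {
  if (!length(selections)) stopf("no feature selections supplied")
  unknown <- setdiff(classifiers, CLASSIFIER_NAMES)
  if (length(unknown)) stopf("unknown classifier '%s'", unknown[1])
  if (is.null(split)) split <- split_data(table, spec)
  sizes <- names(selections)
  grid <- expand.grid(n_features = sizes, classifier = classifiers,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- selections[[grid$n_features[i]]]
    cell <- tryCatch({
      model <- train_classifier(split$train, grid$classifier[i], sel,
                                seed = seed)
      ev <- evaluate_classifier(model, split$test)
      cv <- if (compute_cv)
        cross_validate(split$train, grid$classifier[i], sel,
                       k = spec$k_folds, seed = seed) else NA_real_
      c(as.list(ev$confusion),
        list(accuracy = ev$accuracy, sensitivity = ev$sensitivity,
             specificity = ev$specificity, cv_loss = cv, error = NA_character_))
    }, error = function(e)
      list(TP = NA, FP = NA, TN = NA, FN = NA, accuracy = NA_real_,
           sensitivity = NA_real_, specificity = NA_real_,
           cv_loss = NA_real_, error = conditionMessage(e)))
    cell
  })
  grid$n_features <- as.integer(grid$n_features)
  for (field in c("accuracy", "cv_loss", "sensitivity", "specificity",
                  "TP", "FP", "TN", "FN"))
    grid[[field]] <- vapply(rows, function(r) as.numeric(r[[field]]), 0)
  grid$error <- vapply(rows, function(r) as.character(r[["error"]]), "")
  ok <- which(!is.na(grid$accuracy))
  best <- if (length(ok)) {
    o <- ok[order(-grid$accuracy[ok], grid$cv_loss[ok], ok)]
    grid[o[1], , drop = FALSE]
  } else NULL
  structure(list(grid = grid, best = best,
                 partition = paste(split$test_idx, collapse = ","),
                 n_train = nrow(split$train), n_test = nrow(split$test),
                 spec = spec, seed = seed),
            class = "qeeg_report")
}

#' @export
print.qeeg_report <- function(x, ...) {
  cat("<qeeg_report>", x$n_train, "train /", x$n_test, "test subjects\n")
  acc <- stats::xtabs(accuracy ~ n_features + classifier, x$grid)
  print(round(unclass(acc)[, intersect(CLASSIFIER_NAMES, colnames(acc)),
                           drop = FALSE], 2))
  if (!is.null(x$best))
    cat(sprintf("best: %s with %d features - %.2f%% accuracy (cv loss %.3f)\n",
                x$best$classifier, x$best$n_features, x$best$accuracy,
                x$best$cv_loss))
  invisible(x)
}

#' Write the evaluation grid as CSV (feature counts x classifiers)
#'
#' @param report a `qeeg_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  acc <- stats::xtabs(accuracy ~ n_features + classifier, report$grid)
  df <- as.data.frame.matrix(unclass(acc))
  df <- df[, intersect(CLASSIFIER_NAMES, colnames(df)), drop = FALSE]
  df <- cbind(n_features = rownames(df), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
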