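# Six tree-based ensemble variants over depth-limited regression trees,
# each yielding MSE-split feature importance: per-feature sum of weighted
# mean-squared-error decreases at splits, divided by the ensemble's total
# branch-node count. The final feature set is the intersection of each
# model's top-T features.

ENSEMBLE_VARIANTS <- c("logitboost", "adaboostm1", "gentleboost",
                       "robustboost", "bagging", "totalboost")

# thin wrappers over the compiled tree
fit_tree <- function(X, y, w = rep(1, length(y)), max_depth = 3, min_leaf = 1)
  .tree_fit_cpp(X, as.numeric(y), as.numeric(w), as.integer(max_depth),
                as.integer(min_leaf))

predict_tree <- function(tree, X) .tree_predict_cpp(tree, X)

as_pm1 <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stopf("binary labels required (got %d classes)", nlevels(y))
  ifelse(y == levels(y)[2], 1, -1)
}

#' Train one importance ensemble
#'
#' Fits one of the six tree-ensemble variants on binary labels and returns
#' the fitted ensemble together with its feature-importance table. Variants:
#' `logitboost` (adaptive logistic regression), `adaboostm1` (adaptive
#' boosting), `gentleboost` (gentle adaptive boosting), `robustboost` and
#' `totalboost` (implemented as weight-capped adaptive boosting fallbacks;
#' see Details) and `bagging` (bootstrap aggregation). Importance is the
#' per-feature sum of weighted-MSE decreases over all splits divided by the
#' ensemble's total branch-node count; a feature never split on scores
#' exactly 0.
#'
#' @details The robust and totally-corrective variants follow their boosting
#' skeleton but replace the exact potential-based weight updates with capped
#' AdaBoost weight updates (`robustboost`: per-subject weights capped at
#' 4/n; `totalboost`: projection onto the capped simplex with cap 10/n).
#' This fallback is flagged in the returned object; the selection contract
#' downstream depends only on each model's top-T ranking.
#'
#' @param X numeric matrix or `feature_table` (metadata columns dropped).
#' @param y binary group labels (second factor level is the positive class).
#' @param variant one of the six model names.
#' @param seed integer seed (bootstrap draws; boosting is deterministic).
#' @param n_trees number of base learners (default 100).
#' @param max_depth tree depth limit (default 3).
#' @param learn_rate boosting learning rate (default 0.1).
#' @return Object of class `qeeg_ensemble` with elements `variant`,
#'   `trees`, `alphas`, `importance` (named, non-negative), `n_branch_nodes`
#'   and `seed`.
#' @export
train_importance_ensemble <- function(X, y, variant, seed = 1L,
                                      n_trees = 100, max_depth = 3,
                                      learn_rate = 0.1) {
  if (!variant %in% ENSEMBLE_VARIANTS)
    stopf("unknown ensemble variant '%s'", variant)
  if (inherits(X, "feature_table")) X <- feature_matrix(X)
  X <- as.matrix(X)
  ym <- as_pm1(y)
  n <- nrow(X)
  trees <- list(); alphas <- numeric(0)
  imp <- numeric(ncol(X)); n_branch <- 0L
  add_tree <- function(tr, alpha) {
    trees[[length(trees) + 1]] <<- tr
    alphas[length(alphas) + 1] <<- alpha
    imp <<- imp + tr$importance
    n_branch <<- n_branch + tr$n_branch
  }

  if (variant == "bagging") {
    with_seed(seed, {
      for (t in seq_len(n_trees)) {
        idx <- sample.int(n, n, replace = TRUE)
        tr <- fit_tree(X[idx, , drop = FALSE], ym[idx], max_depth = max_depth)
        add_tree(tr, 1 / n_trees)
      }
    })
    score_type <- "average"
  } else if (variant == "logitboost") {
    Fx <- numeric(n); y01 <- (ym + 1) / 2
    for (t in seq_len(n_trees)) {
      p <- 1 / (1 + exp(-2 * Fx))
      w <- pmax(p * (1 - p), 1e-5)
      z <- pmin(pmax((y01 - p) / w, -4), 4)
      tr <- fit_tree(X, z, w / sum(w), max_depth = max_depth)
      f <- predict_tree(tr, X)
      Fx <- Fx + learn_rate * 0.5 * f
      add_tree(tr, learn_rate * 0.5)
      if (all(sign(Fx) == ym)) break
    }
    score_type <- "additive"
  } else if (variant == "gentleboost") {
    w <- rep(1 / n, n); Fx <- numeric(n)
    for (t in seq_len(n_trees)) {
      tr <- fit_tree(X, ym, w, max_depth = max_depth)
      f <- predict_tree(tr, X)
      Fx <- Fx + learn_rate * f
      add_tree(tr, learn_rate)
      w <- w * exp(-ym * learn_rate * f)
      s <- sum(w); if (s <= 0) break
      w <- w / s
    }
    score_type <- "additive"
  } else {  # adaboostm1 / robustboost / totalboost skeleton
    cap <- switch(variant, robustboost = 4 / n, totalboost = 10 / n, Inf)
    w <- rep(1 / n, n)
    for (t in seq_len(n_trees)) {
      tr <- fit_tree(X, ym, w, max_depth = max_depth)
      pred <- sign(predict_tree(tr, X)); pred[pred == 0] <- 1
      err <- sum(w[pred != ym])
      if (err >= 0.5) break
      err <- max(err, 1e-10)
      alpha <- learn_rate * 0.5 * log((1 - err) / err)
      add_tree(tr, alpha)
      w <- w * exp(-alpha * ym * pred)
      w <- pmin(w / sum(w), cap)
      w <- w / sum(w)
      if (err <= 1e-10) break
    }
    score_type <- "sign"
  }
  if (!length(trees)) stopf("ensemble '%s' fitted no trees", variant)
  importance <- imp / max(n_branch, 1L)
  names(importance) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  structure(list(variant = variant, trees = trees, alphas = alphas,
                 score_type = score_type, importance = importance,
                 n_branch_nodes = n_branch, seed = seed,
                 levels = levels(as.factor(y)),
                 fallback = variant %in% c("robustboost", "totalboost"),
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               learn_rate = learn_rate)),
            class = "qeeg_ensemble")
}

ensemble_score <- function(object, X) {
  X <- as.matrix(X)
  preds <- vapply(seq_along(object$trees), function(t) {
    f <- predict_tree(object$trees[[t]], X)
    if (object$score_type == "sign") {
      s <- sign(f); s[s == 0] <- 1
      object$alphas[t] * s
    } else object$alphas[t] * f
  }, numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  rowSums(preds)
}

#' @export
predict.qeeg_ensemble <- function(object, newdata, type = c("class", "score"),
                                  ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- feature_matrix(newdata)
  sc <- ensemble_score(object, newdata)
  if (type == "score") return(sc)
  factor(ifelse(sc >= 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' @export
print.qeeg_ensemble <- function(x, ...) {
  cat("<qeeg_ensemble>", x$variant, "-", length(x$trees), "trees,",
      x$n_branch_nodes, "branch nodes",
      if (x$fallback) "(capped-weight fallback)" else "", "\n")
  top <- sort(x$importance, decreasing = TRUE)[1:min(5, length(x$importance))]
  cat("  top importances:", paste(sprintf("%s=%.3g", names(top), top),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Importance table of a fitted ensemble
#'
#' @param model a `qeeg_ensemble`.
#' @return data.frame `feature`, `importance` (class `importance_table`)
#'   with the model name, branch-node count and seed as attributes.
#' @export
importance_table <- function(model) {
  stopifnot(inherits(model, "qeeg_ensemble"))
  out <- data.frame(feature = names(model$importance),
                    importance = unname(model$importance),
                    stringsAsFactors = FALSE)
  attr(out, "model") <- model$variant
  attr(out, "n_branch_nodes") <- model$n_branch_nodes
  attr(out, "seed") <- model$seed
  class(out) <- c("importance_table", "data.frame")
  out
}

# ranks (1 = most important), ties broken by canonical feature-name order
importance_ranks <- function(tab) {
  ord <- order(-tab$importance, tab$feature)
  r <- integer(nrow(tab)); r[ord] <- seq_len(nrow(tab))
  stats::setNames(r, tab$feature)
}

top_T <- function(tab, T) {
  r <- importance_ranks(tab)
  names(r)[r <= T]
}

#' Intersection feature selection
#'
#' The final feature set is the intersection of each model's top-`T`
#' features (ties at rank `T` broken by canonical feature-name order),
#' ordered by descending importance via ascending mean rank across models
#' (ties again by feature name). An empty intersection is allowed; the
#' caller must raise `T`.
#'
#' @param tables list of `importance_table`s over an identical feature set
#'   (>= 2 tables).
#' @param T per-model threshold, `1 <= T <=` number of features.
#' @return Object of class `selected_features`: ordered `features`,
#'   `T`, contributing `models`.
#' @export
select_intersection <- function(tables, T) {
  if (length(tables) < 2) stopf("need at least 2 importance tables")
  universes <- lapply(tables, function(t) sort(t$feature))
  if (!all(vapply(universes[-1], identical, TRUE, universes[[1]])))
    stopf("importance tables have mismatched feature universes")
  n_feat <- nrow(tables[[1]])
  if (T < 1 || T > n_feat) stopf("T must be in [1, %d]", n_feat)
  tops <- lapply(tables, top_T, T = T)
  sel <- Reduce(intersect, tops)
  ranks <- vapply(tables, function(t) importance_ranks(t)[sel],
                  numeric(length(sel)))
  if (length(sel) == 1) ranks <- matrix(ranks, nrow = 1)
  mean_rank <- if (length(sel)) rowMeans(ranks) else numeric(0)
  ord <- order(mean_rank, sel)
  structure(list(features = sel[ord], T = T,
                 mean_rank = mean_rank[ord],
                 models = vapply(tables, function(t)
                   attr(t, "model") %||% "unknown", ""),
                 seeds = vapply(tables, function(t)
                   as.integer(attr(t, "seed") %||% NA_integer_), 0L)),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat("<selected_features>", length(x$features), "features at T =", x$T,
      "from", length(x$models), "models\n")
  if (length(x$features)) cat(" ", paste(utils::head(x$features, 10),
                                         collapse = ", "),
                              if (length(x$features) > 10) "..." else "", "\n")
  invisible(x)
}

#' Sweep the intersection threshold to a ladder of feature counts
#'
#' For each target size, finds the smallest per-model threshold `T` whose
#' intersection holds at least that many features, then truncates by mean
#' rank to exactly the target size.
#'
#' @param tables list of `importance_table`s.
#' @param target_sizes ascending positive integers.
#' @return Named list mapping each target size to a `selected_features`.
#' @export
sweep_threshold <- function(tables, target_sizes) {
  if (any(target_sizes < 1)) stopf("target sizes must be >= 1")
  if (is.unsorted(target_sizes)) stopf("target sizes must be ascending")
  n_feat <- nrow(tables[[1]])
  if (max(target_sizes) > n_feat)
    stopf("target size %d unreachable: ceiling is %d features",
          max(target_sizes), n_feat)
  out <- list(); T <- 1
  for (m in target_sizes) {
    sel <- select_intersection(tables, T)
    while (length(sel$features) < m && T < n_feat) {
      T <- T + 1
      sel <- select_intersection(tables, T)
    }
    if (length(sel$features) < m)
      stopf("target size %d unreachable at T = %d", m, n_feat)
    sel$features <- sel$features[seq_len(m)]
    sel$mean_rank <- sel$mean_rank[seq_len(m)]
    out[[as.character(m)]] <- sel
  }
  out
}
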