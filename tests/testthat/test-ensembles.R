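# brute-force single-stump oracle: best split of one regression stump and
# its MSE decrease, by explicit enumeration over all split points
stump_oracle <- function(X, y) {
  best <- list(gain = 0, feature = NA, threshold = NA)
  n <- length(y)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    for (k in seq_len(length(xs) - 1)) {
      thr <- (xs[k] + xs[k + 1]) / 2
      l <- y[X[, j] < thr]; r <- y[X[, j] >= thr]
      gain <- (sse(y) - sse(l) - sse(r)) / n   # weighted-MSE decrease, w = 1/n
      if (gain > best$gain)
        best <- list(gain = gain, feature = j, threshold = thr)
    }
  }
  best
}

test_that("single-stump importance equals the hand-enumerated MSE decrease", {
  X <- cbind(f1 = c(1, 2, 3, 10, 11, 12), f2 = c(5, 1, 4, 2, 6, 3))
  y <- c(0, 0, 0, 1, 1, 1)
  oracle <- stump_oracle(X, ifelse(y == 1, 1, -1))  # boosting's +/-1 coding
  m <- train_importance_ensemble(X, y, "adaboostm1", seed = 1, n_trees = 1,
                                 max_depth = 1, learn_rate = 1)
  expect_equal(m$n_branch_nodes, 1)
  expect_equal(unname(m$importance["f1"]), oracle$gain, tolerance = 1e-12)
  expect_equal(unname(m$importance["f2"]), 0)
  expect_equal(m$trees[[1]]$feature[1] + 1, oracle$feature)
  expect_equal(m$trees[[1]]$threshold[1], oracle$threshold)
})

test_that("constant features score exactly zero in every variant", {
  set.seed(2)
  X <- cbind(info = c(rnorm(20), rnorm(20, 3)), const = rep(2, 40),
             noise = rnorm(40))
  y <- rep(c("normal", "depression"), each = 20)
  for (v in qeegscreen:::ENSEMBLE_VARIANTS) {
    m <- train_importance_ensemble(X, y, v, seed = 3, n_trees = 20)
    expect_identical(unname(m$importance["const"]), 0)
  }
})

test_that("a perfectly separating feature dominates importance in all variants", {
  set.seed(4)
  X <- cbind(f1 = c(rnorm(20, -4), rnorm(20, 4)),
             matrix(rnorm(40 * 9), 40, dimnames = list(NULL, paste0("n", 1:9))))
  y <- rep(c(0, 1), each = 20)
  for (v in qeegscreen:::ENSEMBLE_VARIANTS) {
    m <- train_importance_ensemble(X, y, v, seed = 5, n_trees = 30)
    expect_equal(names(which.max(m$importance)), "f1")
  }
})

test_that("unknown variants and single-class labels error", {
  X <- matrix(rnorm(20), 10)
  expect_error(train_importance_ensemble(X, rep(1, 10), "adaboostm1"),
               "binary")
  expect_error(train_importance_ensemble(X, rep(c(0, 1), 5), "superboost"),
               "unknown ensemble")
})

test_that("ensemble training and prediction are deterministic given seeds", {
  set.seed(6)
  X <- matrix(rnorm(60 * 8), 60, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(0, 1), 30)
  for (v in c("bagging", "logitboost")) {
    a <- train_importance_ensemble(X, y, v, seed = 7, n_trees = 15)
    b <- train_importance_ensemble(X, y, v, seed = 7, n_trees = 15)
    expect_identical(a$importance, b$importance)
    expect_identical(predict(a, X), predict(b, X))
  }
})

random_tables <- function(n_models = 6, n_feat = 40, seed = 1) {
  set.seed(seed)
  feats <- sprintf("f%02d", seq_len(n_feat))
  lapply(seq_len(n_models), function(i) {
    out <- data.frame(feature = feats, importance = runif(n_feat),
                      stringsAsFactors = FALSE)
    attr(out, "model") <- paste0("m", i)
    class(out) <- c("importance_table", "data.frame")
    out
  })
}

test_that("intersection selection matches a brute-force oracle", {
  tabs <- random_tables(6, 40, seed = 8)
  sel <- select_intersection(tabs, T = 10)
  # independent oracle: explicit sorts and set intersection
  oracle <- Reduce(intersect, lapply(tabs, function(t)
    t$feature[order(-t$importance, t$feature)][1:10]))
  expect_setequal(sel$features, oracle)
  # permutation invariance and weak shrinkage
  sel_rev <- select_intersection(rev(tabs), T = 10)
  expect_setequal(sel_rev$features, sel$features)
  sel5 <- select_intersection(tabs[1:5], T = 10)
  expect_true(all(sel$features %in% sel5$features))
})

test_that("identical rankings give exactly the top T; disjoint tops are empty", {
  tabs <- random_tables(2, 30, seed = 9)
  tabs[[2]]$importance <- tabs[[1]]$importance
  sel <- select_intersection(tabs, T = 12)
  expect_identical(sel$features,
                   tabs[[1]]$feature[order(-tabs[[1]]$importance,
                                           tabs[[1]]$feature)][1:12])
  # force disjoint top-5 sets
  t2 <- tabs
  t2[[1]]$importance <- c(rep(1, 5), rep(0, 25))
  t2[[2]]$importance <- c(rep(0, 25), rep(1, 5))
  expect_length(select_intersection(t2, T = 5)$features, 0)
  expect_error(select_intersection(list(tabs[[1]]), 3), "at least 2")
  bad <- tabs; bad[[2]]$feature[1] <- "zz"
  expect_error(select_intersection(bad, 3), "mismatched")
})

test_that("threshold sweeping matches an exhaustive T scan", {
  tabs <- random_tables(6, 30, seed = 10)
  sels <- sweep_threshold(tabs, c(3, 5))
  for (m in c(3, 5)) {
    # oracle: scan T upward, take the first intersection of size >= m
    T_star <- NA
    for (T in 1:30) {
      size <- length(Reduce(intersect, lapply(tabs, function(t)
        t$feature[order(-t$importance, t$feature)][1:T])))
      if (size >= m) { T_star <- T; break }
    }
    sel <- sels[[as.character(m)]]
    expect_equal(sel$T, T_star)
    expect_length(sel$features, m)
  }
  expect_true(all(sels[["3"]]$features %in% sels[["5"]]$features))
  expect_error(sweep_threshold(tabs, 0), ">= 1")
  expect_error(sweep_threshold(tabs, c(5, 3)), "ascending")
  expect_error(sweep_threshold(tabs, 31), "unreachable")
})

test_that("importance bookkeeping: scores are finite, non-negative, conserved", {
  set.seed(11)
  X <- matrix(rnorm(80 * 6), 80, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(0, 1), 40)
  m <- train_importance_ensemble(X, y, "gentleboost", seed = 12, n_trees = 10)
  expect_true(all(is.finite(m$importance)) && all(m$importance >= 0))
  # sum(importance) * n_branch equals the total accumulated gain over trees
  total_gain <- sum(vapply(m$trees, function(t) sum(t$importance), 0))
  expect_equal(sum(m$importance) * m$n_branch_nodes, total_gain,
               tolerance = 1e-9)
})

test_that("selection recovers planted band biomarkers on cohort-scale data", {
  trend <- norm_trend_config()
  model <- fit_normative_model(generate_normative_powers(200, trend, 40))
  hits <- vapply(1:2, function(sd) {
    co <- generate_cohort(seed = sd)
    pow <- generate_cohort_powers(co, seed = sd + 50, trend = trend)
    ft <- build_feature_table(co, pow, model)
    X <- qeegscreen:::feature_matrix(ft)
    tabs <- lapply(qeegscreen:::ENSEMBLE_VARIANTS, function(v)
      importance_table(train_importance_ensemble(X, ft$group, v,
                                                 seed = sd, n_trees = 50)))
    sel <- sweep_threshold(tabs, 28)[["28"]]
    planted <- grepl("Beta2|Beta3|Alpha2", sel$features)
    mean(planted)
  }, 0)
  expect_gte(mean(hits), 0.7)
})
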