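# The ten screening classifiers with pinned hyperparameters. Labels are a
# two-level factor with "depression" as the positive (second) class where
# present. SVM-family models are least-squares formulations (closed-form,
# deterministic); ECOC on binary labels degenerates to its single base SVM.

CLASSIFIER_NAMES <- c("LB", "ECOC", "DA", "SVM", "GK", "KNN", "rSVM",
                      "NB", "DT", "AdaM1")

group_factor <- function(y) {
  y <- as.character(y)
  lev <- if (all(y %in% c("normal", "depression")))
    c("normal", "depression") else sort(unique(y))
  factor(y, levels = lev)
}

scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sdv, `/`), mu = mu, sd = sdv)
}
scale_apply <- function(sc, X) sweep(sweep(X, 2, sc$mu), 2, sc$sd, `/`)

rbf_sigma2 <- function(X) {
  n <- nrow(X)
  idx <- if (n > 100) seq(1, n, length.out = 100) else seq_len(n)
  d2 <- as.vector(stats::dist(X[idx, , drop = FALSE])^2)
  s <- median(d2)
  if (!is.finite(s) || s <= 0) 1 else s
}

ls_svm_fit <- function(K, ym, C = 1) {
  n <- nrow(K)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- solve(M, c(0, ym))
  list(b = sol[1], alpha = sol[-1])
}

rbf_kernel <- function(A, B, sigma2) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * sigma2))
}

#' Train one of the ten screening classifiers
#'
#' Classifier names and pinned configurations: `LB` (LogitBoost, 100 stumps,
#' rate 0.1), `AdaM1` (AdaBoostM1, 100 stumps, rate 0.1), `DT` (single
#' depth-10 tree), `NB` (Gaussian naive Bayes), `KNN` (k = 5, Euclidean on
#' standardized features), `DA` (linear discriminant analysis), `SVM`
#' (least-squares SVM, RBF kernel with median-heuristic bandwidth, C = 1),
#' `ECOC` (degenerate binary error-correcting output codes wrapping the base
#' SVM), `rSVM` (L2-regularized linear least-squares SVM, lambda = 1), `GK`
#' (random-Fourier-feature Gaussian kernel approximation + ridge, 200
#' features). The model is trained only on the named feature columns.
#'
#' @param train a `feature_table` (with `group` labels).
#' @param name classifier name.
#' @param features character vector of feature columns or a
#'   `selected_features` object (non-empty).
#' @param seed integer seed (used by the random-feature models).
#' @return Object of class `qeeg_classifier`.
#' @export
train_classifier <- function(train, name, features, seed = 1L) {
  if (!name %in% CLASSIFIER_NAMES) stopf("unknown classifier '%s'", name)
  if (inherits(features, "selected_features")) features <- features$features
  if (!length(features)) stopf("empty feature set")
  missing <- setdiff(features, names(train))
  if (length(missing)) stopf("features not in table: %s", missing[1])
  y <- group_factor(train$group)
  if (nlevels(droplevels(y)) < 2) stopf("training labels are single-class")
  X <- feature_matrix(train, features)
  ym <- ifelse(y == levels(y)[2], 1, -1)
  sc <- scale_train(X)
  Z <- sc$X

  fit <- switch(
    name,
    LB = train_importance_ensemble(X, y, "logitboost", seed = seed,
                                   n_trees = 100, max_depth = 1),
    AdaM1 = train_importance_ensemble(X, y, "adaboostm1", seed = seed,
                                      n_trees = 100, max_depth = 1),
    DT = fit_tree(X, ym, max_depth = 10, min_leaf = 1),
    NB = {
      stats_by <- lapply(levels(y), function(lv) {
        Xi <- X[y == lv, , drop = FALSE]
        list(mu = colMeans(Xi), sd = pmax(apply(Xi, 2, sd), 1e-6),
             logprior = log(mean(y == lv)))
      })
      names(stats_by) <- levels(y)
      stats_by
    },
    KNN = list(Z = Z, y = y, k = 5),
    DA = MASS::lda(Z, grouping = y),
    SVM = ,
    ECOC = {
      s2 <- rbf_sigma2(Z)
      list(svm = ls_svm_fit(rbf_kernel(Z, Z, s2), ym, C = 1),
           Z = Z, sigma2 = s2)
    },
    rSVM = {
      Xi <- cbind(1, Z)
      beta <- solve(crossprod(Xi) + diag(c(0, rep(1, ncol(Z)))),
                    crossprod(Xi, ym))
      list(beta = beta)
    },
    GK = with_seed(seed, {
      s2 <- rbf_sigma2(Z)
      D <- 200
      W <- matrix(rnorm(ncol(Z) * D, sd = 1 / sqrt(s2)), ncol(Z), D)
      b <- runif(D, 0, 2 * pi)
      Phi <- sqrt(2 / D) * cos(sweep(Z %*% W, 2, b, `+`))
      Xi <- cbind(1, Phi)
      beta <- solve(crossprod(Xi) + diag(c(0, rep(1, D))),
                    crossprod(Xi, ym))
      list(W = W, b = b, D = D, beta = beta)
    }))

  structure(list(name = name, fit = fit, features = features,
                 scaling = sc, levels = levels(y), seed = seed),
            class = "qeeg_classifier")
}

#' @export
predict.qeeg_classifier <- function(object, newdata, ...) {
  X <- feature_matrix(newdata, object$features)
  Z <- scale_apply(object$scaling, X)
  lev <- object$levels
  to_factor <- function(score) factor(ifelse(score >= 0, lev[2], lev[1]),
                                      levels = lev)
  switch(
    object$name,
    LB = ,
    AdaM1 = predict(object$fit, X),
    DT = {
      s <- predict_tree(object$fit, X)
      to_factor(s)
    },
    NB = {
      ll <- sapply(object$fit, function(st)
        rowSums(stats::dnorm(X, matrix(st$mu, nrow(X), ncol(X), byrow = TRUE),
                             matrix(st$sd, nrow(X), ncol(X), byrow = TRUE),
                             log = TRUE)) + st$logprior)
      if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
      factor(lev[max.col(ll, ties.method = "first")], levels = lev)
    },
    KNN = {
      d2 <- outer(rowSums(Z^2), rowSums(object$fit$Z^2), `+`) -
        2 * tcrossprod(Z, object$fit$Z)
      pred <- apply(d2, 1, function(d) {
        nb <- order(d)[seq_len(object$fit$k)]
        votes <- table(object$fit$y[nb])
        top <- names(votes)[votes == max(votes)]
        if (length(top) == 1) top else as.character(object$fit$y[nb[1]])
      })
      factor(pred, levels = lev)
    },
    DA = predict(object$fit, Z)$class,
    SVM = ,
    ECOC = {
      K <- rbf_kernel(Z, object$fit$Z, object$fit$sigma2)
      to_factor(drop(K %*% object$fit$svm$alpha) + object$fit$svm$b)
    },
    rSVM = to_factor(drop(cbind(1, Z) %*% object$fit$beta)),
    GK = {
      Phi <- sqrt(2 / object$fit$D) *
        cos(sweep(Z %*% object$fit$W, 2, object$fit$b, `+`))
      to_factor(drop(cbind(1, Phi) %*% object$fit$beta))
    })
}

#' @export
print.qeeg_classifier <- function(x, ...) {
  cat("<qeeg_classifier>", x$name, "on", length(x$features), "features\n")
  invisible(x)
}
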