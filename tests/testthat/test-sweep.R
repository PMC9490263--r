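test_that("the 80/20 stratified split gives 39 test subjects at n = 196", {
  co <- generate_cohort(seed = 41)
  tab <- cbind(co, f1 = rnorm(nrow(co)))
  class(tab) <- c("feature_table", "data.frame")
  sp <- split_data(tab, split_spec(seed = 1))
  expect_equal(nrow(sp$test), 39)
  expect_equal(nrow(sp$train), 157)
  expect_equal(sum(sp$test$group == "depression"), 23)   # floor(0.2 x 116)
  expect_equal(sum(sp$test$group == "normal"), 16)       # floor(0.2 x 80)
})

test_that("splits are disjoint, exhaustive and deterministic", {
  tab <- toy_table(n_per = 5, seed = 42)
  sp <- split_data(tab, split_spec(seed = 3))
  expect_equal(nrow(sp$test), 2)
  expect_equal(nrow(sp$train), 8)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id), tab$subject_id)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  sp2 <- split_data(tab, split_spec(seed = 3))
  expect_identical(sp$test_idx, sp2$test_idx)
  sp3 <- split_data(tab, split_spec(seed = 4))
  expect_false(identical(sp$test_idx, sp3$test_idx))
})

test_that("degenerate splits error out", {
  tab <- toy_table(n_per = 2, seed = 43)
  one <- tab[tab$group == "normal", ]
  expect_error(split_data(one, split_spec()), "both classes")
  expect_error(split_spec(train_fraction = 1.2), "train_fraction")
  expect_error(split_spec(k_folds = 1), "k_folds")
})

make_selections <- function(sizes, pool) {
  out <- lapply(sizes, function(m)
    structure(list(features = pool[seq_len(m)], T = m,
                   models = "fixture"), class = "selected_features"))
  names(out) <- as.character(sizes)
  out
}

test_that("a 1x1 grid evaluates and carries the metric identities", {
  tab <- toy_table(n_per = 25, effect = 2, seed = 44)
  sels <- make_selections(2, c("f1", "noise1"))
  rep1 <- run_sweep(tab, sels, classifiers = "NB",
                    spec = split_spec(seed = 5, k_folds = 5), seed = 6)
  expect_equal(nrow(rep1$grid), 1)
  g <- rep1$grid
  expect_equal(g$accuracy, 100 * (g$TP + g$TN) / (g$TP + g$FP + g$TN + g$FN))
  expect_equal(g$sensitivity, g$TP / (g$TP + g$FN))
  expect_equal(g$specificity, g$TN / (g$TN + g$FP))
  expect_true(g$cv_loss >= 0 && g$cv_loss <= 1)
})

test_that("linearly separable features drive all cells to 100%", {
  tab <- toy_table(n_per = 25, effect = 10, seed = 45)
  sels <- make_selections(c(1, 2), c("f1", "noise1"))
  rep1 <- run_sweep(tab, sels, classifiers = c("DA", "SVM", "NB", "KNN"),
                    spec = split_spec(seed = 7, k_folds = 5), seed = 8,
                    compute_cv = FALSE)
  expect_true(all(rep1$grid$accuracy == 100))
})

test_that("the whole grid shares one partition and the best cell follows the tie-break", {
  tab <- toy_table(n_per = 30, effect = 1.2, seed = 46)
  sels <- make_selections(c(1, 3), c("f1", "noise1", "noise2"))
  rep1 <- run_sweep(tab, sels, classifiers = c("DA", "NB", "KNN"),
                    spec = split_spec(seed = 9, k_folds = 5), seed = 10)
  expect_equal(length(unique(rep1$partition)), 1)
  g <- rep1$grid
  top <- max(g$accuracy, na.rm = TRUE)
  cand <- g[g$accuracy == top, ]
  expect_equal(rep1$best$cv_loss, min(cand$cv_loss))
  # identical call reproduces the best cell exactly
  rep2 <- run_sweep(tab, sels, classifiers = c("DA", "NB", "KNN"),
                    spec = split_spec(seed = 9, k_folds = 5), seed = 10)
  expect_identical(rep1$best, rep2$best)
  expect_identical(rep1$partition, rep2$partition)
})

test_that("cell failures are recorded while the grid completes", {
  tab <- toy_table(n_per = 10, seed = 47)
  sels <- c(make_selections(1, "f1"),
            make_selections(2, c("f1", "gone"))["2"])
  names(sels) <- c("1", "2")
  rep1 <- run_sweep(tab, sels, classifiers = "NB",
                    spec = split_spec(seed = 11, k_folds = 3), seed = 12)
  expect_true(any(!is.na(rep1$grid$error) & rep1$grid$error != "NA"))
  expect_true(any(!is.na(rep1$grid$accuracy)))
})

test_that("reports serialize to a feature-count x classifier CSV", {
  tab <- toy_table(n_per = 20, effect = 3, seed = 48)
  sels <- make_selections(c(1, 2), c("f1", "noise1"))
  rep1 <- run_sweep(tab, sels, classifiers = c("DA", "NB"),
                    spec = split_spec(seed = 13, k_folds = 3), seed = 14,
                    compute_cv = FALSE)
  path <- tempfile(fileext = ".csv")
  write_report(rep1, path)
  back <- read.csv(path)
  expect_identical(names(back), c("n_features", "DA", "NB"))
  expect_equal(nrow(back), 2)
})
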