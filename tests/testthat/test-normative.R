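test_that("the fit recovers a linear age trend within 25%", {
  trend <- norm_trend_config(slopes = c(Delta = -0.005, Theta = -0.005,
                                        Alpha1 = -0.005, Alpha2 = -0.005,
                                        Beta1 = -0.005, Beta2 = -0.005,
                                        Beta3 = -0.005, Gamma = -0.005),
                             sex_offset = 0)
  tab <- generate_normative_powers(400, trend, seed = 4)
  model <- fit_normative_model(tab, degree = 1)
  abs_cells <- grep("^Abs_", model$cells, value = TRUE)
  slopes <- vapply(c("M", "F"), function(sx)
    mean(coef(model, sx)[2, abs_cells]), 0)
  for (b in slopes) expect_lt(abs(b - (-0.005)), 0.25 * 0.005)
})

test_that("a constant-mean normative world yields near-zero trends", {
  trend <- norm_trend_config(slopes = c(Delta = 0, Theta = 0, Alpha1 = 0,
                                        Alpha2 = 0, Beta1 = 0, Beta2 = 0,
                                        Beta3 = 0, Gamma = 0),
                             sex_offset = 0)
  tab <- generate_normative_powers(400, trend, seed = 5)
  model <- fit_normative_model(tab, degree = 1)
  co <- coef(model, "F")[2, grep("^Abs_", model$cells)]
  # slope standard error ~ sigma / (sd(age) * sqrt(n)) on the log10 scale
  se <- trend$sigma / (sd(tab$age[tab$sex == "F"]) *
                         sqrt(sum(tab$sex == "F")))
  expect_lt(mean(abs(co) < 2 * se), 1.01)
  expect_gt(mean(abs(co) < 2 * se), 0.90)
})

test_that("an under-represented sex is gated unfit while the other fits", {
  trend <- norm_trend_config()
  tab <- generate_normative_powers(120, trend, seed = 6)
  tab <- tab[c(which(tab$sex == "M")[1:10], which(tab$sex == "F")), ]
  model <- fit_normative_model(tab, min_n = 30)
  expect_false(model$sexes$M$fit)
  expect_true(model$sexes$F$fit)
  expect_error(zscore(1, 40, "M", "Abs_Delta_Fz", model), "unfit")
  expect_silent(zscore(1, 40, "F", "Abs_Delta_Fz", model))
})

test_that("z-scores are exactly 0 at the fitted mean and 1 at +1 spread", {
  trend <- norm_trend_config()
  tab <- generate_normative_powers(200, trend, seed = 7)
  model <- fit_normative_model(tab)
  cell <- "Abs_Alpha2_Pz"
  s <- model$sexes$F
  mu <- qeegscreen:::normative_mean(model, "F", cell, 50)
  expect_equal(zscore(10^mu, 50, "F", cell, model), 0, tolerance = 1e-10)
  expect_equal(zscore(10^(mu + s$spread[[cell]]), 50, "F", cell, model), 1,
               tolerance = 1e-10)
  # strictly increasing in the raw value
  v <- 10^seq(mu - 1, mu + 1, length.out = 7)
  expect_true(all(diff(zscore(v, 50, "F", cell, model)) > 0))
  expect_error(zscore(1, 120, "F", cell, model), "fitted range")
  expect_error(zscore(1, 40, "F", "Abs_Delta_XX", model), "unknown")
})

test_that("held-out z-scores are calibrated on average and near-normal", {
  trend <- norm_trend_config()
  fitted <- fit_normative_model(generate_normative_powers(400, trend, 8))
  held <- generate_normative_powers(1000, trend, seed = 88)
  z <- qeegscreen:::zscore_table(fitted, held)
  expect_false(anyNA(z))
  expect_lt(abs(mean(colMeans(z))), 0.05)
  expect_lt(abs(mean(apply(z, 2, sd)) - 1), 0.07)
  # Kolmogorov distance to N(0,1) for a few absolute-power cells
  for (cell in c("Abs_Delta_Fz", "Abs_Beta3_O2", "Abs_Alpha1_Cz")) {
    zz <- z[, sub("^Abs_", "Abs_zscore_", cell)]
    d <- suppressWarnings(ks.test(zz, "pnorm")$statistic)
    expect_lt(unname(d), 0.06)
  }
})

test_that("model fitting is deterministic and survives a JSON round-trip", {
  trend <- norm_trend_config()
  tab <- generate_normative_powers(150, trend, seed = 9)
  m1 <- fit_normative_model(tab)
  m2 <- fit_normative_model(tab)
  expect_identical(m1, m2)
  path <- tempfile(fileext = ".json")
  write_normative_model(m1, path)
  m3 <- read_normative_model(path)
  expect_equal(coef(m3, "F"), coef(m1, "F"), tolerance = 1e-12)
  expect_equal(m3$sexes$M$spread, m1$sexes$M$spread, tolerance = 1e-12)
  expect_equal(zscore(2, 33, "M", "Rel_Beta2_C3", m3),
               zscore(2, 33, "M", "Rel_Beta2_C3", m1), tolerance = 1e-10)
})

test_that("sexes with identical generator trends give matching models", {
  trend <- norm_trend_config(sex_offset = 0)
  tab <- generate_normative_powers(600, trend, seed = 10)
  model <- fit_normative_model(tab, degree = 1)
  cells <- grep("^Abs_", model$cells, value = TRUE)
  # intercept difference across sexes should be fit noise around zero
  d <- coef(model, "M")[1, cells] - coef(model, "F")[1, cells]
  expect_lt(abs(mean(d)), 0.05)
})
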