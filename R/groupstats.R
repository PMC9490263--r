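# Normality-gated two-group comparison per (channel, band, kind) cell:
# Shapiro-Wilk for small groups / Lilliefors-corrected Kolmogorov-Smirnov
# for large ones decides between Welch's t-test and the Mann-Whitney U-test.
# Per-cell significance is uncorrected p < 0.05, mirroring per-electrode
# starring; a Benjamini-Hochberg option exists behind a flag.

# Lilliefors test p-value via the Dallal-Wilkinson (1986) approximation,
# the standard closed form for the KS statistic with estimated mean/SD.
lilliefors_test <- function(x) {
  n <- length(x)
  if (n < 4) stopf("Lilliefors test needs n >= 4")
  s <- sd(x)
  if (s == 0) stopf("constant sample is degenerate for normality testing")
  z <- sort((x - mean(x)) / s)
  p_hat <- pnorm(z)
  d_plus <- max(seq_len(n) / n - p_hat)
  d_minus <- max(p_hat - (seq_len(n) - 1) / n)
  d <- max(d_plus, d_minus)
  # Dallal-Wilkinson: for n > 100 rescale D and use n = 100
  kd <- if (n > 100) d * (n / 100)^0.49 else d
  nd <- if (n > 100) 100 else n
  p <- exp(-7.01256 * kd^2 * (nd + 2.78019) +
             2.99587 * kd * sqrt(nd + 2.78019) - 0.122119 +
             0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    # Stephens' modification for the upper tail
    kk <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * d
    p <- if (kk <= 0.302) 1
    else if (kk <= 0.5) 2.76773 - 19.828315 * kk + 80.709644 * kk^2 -
      138.55152 * kk^3 + 81.218052 * kk^4
    else if (kk <= 0.9) -4.901232 + 40.662806 * kk - 97.490286 * kk^2 +
      94.029866 * kk^3 - 32.355711 * kk^4
    else if (kk <= 1.31) 6.198765 - 19.558097 * kk + 23.186922 * kk^2 -
      12.234627 * kk^3 + 2.423045 * kk^4
    else 0
  }
  min(max(p, 0), 1)
}

#' Test a sample for normality
#'
#' Shapiro-Wilk for samples of 50 or fewer, the Lilliefors-corrected
#' Kolmogorov-Smirnov test for larger samples.
#'
#' @param sample numeric vector, n >= 3, non-constant.
#' @return p-value in `[0, 1]`.
#' @export
test_normality <- function(sample) {
  n <- length(sample)
  if (n < 3) stopf("normality testing needs n >= 3")
  if (sd(sample) == 0) stopf("constant sample is degenerate for normality testing")
  if (n <= 50) shapiro.test(sample)$p.value else lilliefors_test(sample)
}

#' Normality-gated two-group comparison for one cell
#'
#' Welch's two-sided t-test when BOTH groups pass normality at
#' `alpha_norm`, otherwise the two-sided Mann-Whitney U-test. Direction is
#' taken from the group means (t) or rank sums (U), with group B playing
#' the depression role.
#'
#' @param groupA,groupB numeric vectors (normal and depression samples),
#'   each n >= 3 and non-constant.
#' @param alpha_norm normality-gate level (default 0.05).
#' @param alpha significance level for the comparison (default 0.05).
#' @return list of class `group_stat`: means, SDs, normality p-values,
#'   `test_used`, `p_value`, `significant`, `direction`.
#' @export
compare_cell <- function(groupA, groupB, alpha_norm = 0.05, alpha = 0.05) {
  if (length(groupA) < 3 || length(groupB) < 3)
    stopf("both groups need n >= 3")
  if (sd(groupA) == 0 || sd(groupB) == 0)
    stopf("constant group is degenerate")
  pA <- test_normality(groupA); pB <- test_normality(groupB)
  normal_ok <- pA > alpha_norm && pB > alpha_norm
  if (normal_ok) {
    ht <- t.test(groupA, groupB)          # Welch, two-sided
    test_used <- "t_test"
    higher <- mean(groupB) > mean(groupA)
  } else {
    ht <- suppressWarnings(wilcox.test(groupA, groupB))
    test_used <- "mann_whitney"
    # W = rank-sum statistic of A over B; small W => B stochastically larger
    higher <- ht$statistic < length(groupA) * length(groupB) / 2
  }
  p <- unname(ht$p.value)
  structure(list(mean_A = mean(groupA), sd_A = sd(groupA),
                 mean_B = mean(groupB), sd_B = sd(groupB),
                 normality_p = c(A = pA, B = pB), test_used = test_used,
                 p_value = p, significant = p < alpha,
                 direction = if (p >= alpha) "none"
                 else if (higher) "depression_higher" else "depression_lower"),
            class = "group_stat")
}

#' Per-cell group analysis over a feature table
#'
#' Runs [compare_cell()] for every (channel, band, kind) cell of the
#' requested raw kinds over all 8 bands, normal group vs depression group,
#' and summarizes per band/kind which electrodes are flagged significant
#' and in which direction (the shape of per-electrode starred summary
#' tables).
#'
#' @param features a data.frame with `group` and `Abs_*`/`Rel_*` columns
#'   (e.g. from [band_power_table()] for all 8 bands, or a `feature_table`,
#'   whose gamma columns are absent).
#' @param kinds feature kinds to analyze, subset of `c("Abs", "Rel")`.
#' @param bands bands to analyze; defaults to every band of the scheme
#'   whose columns are present in `features`.
#' @param bh_correct apply Benjamini-Hochberg correction across cells
#'   (default `FALSE`, matching uncorrected per-electrode starring).
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `group_analysis`: one row per cell with
#'   means, SDs, `test_used`, `p_value`, `significant`, `direction`.
#' @export
run_group_analysis <- function(features, kinds = c("Abs", "Rel"),
                               bands = NULL, bh_correct = FALSE,
                               alpha = 0.05) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (!all(c("normal", "depression") %in% features$group))
    stopf("feature table must contain both groups")
  ia <- features$group == "normal"; ib <- features$group == "depression"
  bands <- bands %||% qeeg_bands()$band[vapply(qeeg_bands()$band, function(b)
    paste(kinds[1], b, qeeg_montage()[1], sep = "_") %in% names(features),
    TRUE)]
  cells <- expand.grid(channel = qeeg_montage(), band = bands,
                       kind = kinds, stringsAsFactors = FALSE)
  cols <- paste(cells$kind, cells$band, cells$channel, sep = "_")
  missing <- setdiff(cols, names(features))
  if (length(missing)) stopf("feature table lacks cell column %s", missing[1])
  res <- lapply(cols, function(cl)
    compare_cell(features[[cl]][ia], features[[cl]][ib], alpha = alpha))
  out <- cbind(cells, data.frame(
    normal_mean = vapply(res, `[[`, 0, "mean_A"),
    normal_sd = vapply(res, `[[`, 0, "sd_A"),
    dep_mean = vapply(res, `[[`, 0, "mean_B"),
    dep_sd = vapply(res, `[[`, 0, "sd_B"),
    test_used = vapply(res, `[[`, "", "test_used"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE))
  if (bh_correct) out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$dep_mean > out$normal_mean,
                                 "depression_higher", "depression_lower"))
  # recover rank-based direction for Mann-Whitney cells
  mw <- which(out$significant & out$test_used == "mann_whitney")
  for (k in mw) out$direction[k] <- res[[k]]$direction
  class(out) <- c("group_analysis", "data.frame")
  out
}

#' @export
print.group_analysis <- function(x, ...) {
  cat("<group_analysis>", nrow(x), "cells,", sum(x$significant),
      "significant\n")
  sig <- x[x$significant, ]
  if (nrow(sig)) {
    s <- aggregate(channel ~ band + kind + direction, sig,
                   function(ch) paste(ch, collapse = " "))
    print(s, row.names = FALSE)
  }
  invisible(x)
}

#' Topographic summary for one band and kind
#'
#' Extracts the 19-electrode group-mean values and significance mask in
#' fixed montage order, optionally rendering an interpolated scalp map to a
#' PNG file.
#'
#' @param results a `group_analysis`.
#' @param band,kind cell selectors.
#' @param file optional PNG path; when given, a two-panel scalp map
#'   (normal / depression group means, significant electrodes marked) is
#'   written.
#' @return list with `channels`, `normal_mean`, `dep_mean`, `significant`
#'   (logical mask), `direction`.
#' @export
topomap_summary <- function(results, band, kind, file = NULL) {
  sel <- results$band == band & results$kind == kind
  sub <- results[sel, ]
  if (!all(qeeg_montage() %in% sub$channel))
    stopf("results do not cover all 19 electrodes for %s %s", kind, band)
  sub <- sub[match(qeeg_montage(), sub$channel), ]
  out <- list(channels = qeeg_montage(),
              normal_mean = stats::setNames(sub$normal_mean, sub$channel),
              dep_mean = stats::setNames(sub$dep_mean, sub$channel),
              significant = stats::setNames(sub$significant, sub$channel),
              direction = stats::setNames(sub$direction, sub$channel),
              band = band, kind = kind)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
    for (panel in c("normal_mean", "dep_mean"))
      draw_topomap(out[[panel]], out$significant,
                   main = sprintf("%s %s - %s", kind, band,
                                  sub("_mean", "", panel)))
  }
  out
}

# crude inverse-distance-weighted scalp interpolation on the unit circle
draw_topomap <- function(values, mask, main = "") {
  xy <- montage_coords()
  g <- seq(-1.05, 1.05, length.out = 60)
  grid <- expand.grid(x = g, y = g)
  inside <- grid$x^2 + grid$y^2 <= 1.05^2
  z <- rep(NA_real_, nrow(grid))
  d2 <- outer(grid$x[inside], xy[, "x"], `-`)^2 +
    outer(grid$y[inside], xy[, "y"], `-`)^2
  w <- 1 / (d2 + 0.01)
  z[inside] <- (w %*% values) / rowSums(w)
  graphics::image(g, g, matrix(z, length(g)), axes = FALSE, asp = 1,
                  col = grDevices::hcl.colors(64, "viridis"), main = main,
                  xlab = "", ylab = "")
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
  graphics::points(xy[, "x"], xy[, "y"], pch = ifelse(mask, 8, 21),
                   bg = "white", cex = 1.1)
  graphics::text(xy[, "x"], xy[, "y"] - 0.12, rownames(xy), cex = 0.7)
}
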