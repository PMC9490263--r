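test_that("zero profile with no artifacts yields an all-zero recording", {
  prof <- quiet_profile(mean_mat = 0)
  rec <- generate_eeg(fixture_subject(), prof, duration = 10, seed = 1)
  expect_equal(dim(rec$data), c(19, 2500))
  expect_true(all(rec$data == 0))
})

test_that("a single band target is realized within tolerance, others near zero", {
  prof <- quiet_profile(mean_mat = 0)
  prof$mean["Fz", "Alpha1"] <- 1
  rec <- generate_eeg(fixture_subject(), prof, duration = 300, seed = 2)
  # independent full-length rectangular periodogram oracle (leakage-free
  # for band-limited content; Welch/Hann smears a few % across band edges)
  fz <- which(qeeg_montage() == "Fz")
  n <- ncol(rec$data); fs <- rec$fs
  x <- rec$data[fz, ] - mean(rec$data[fz, ])
  pg <- Mod(fft(x))^2 / n^2                  # power per DFT bin, sums to var
  f <- pmin((0:(n - 1)) * fs / n, fs - (0:(n - 1)) * fs / n)
  band_int <- function(lo, hi) sum(pg[f >= lo & f < hi])
  alpha1 <- band_int(8, 10)
  expect_lt(abs(alpha1 - 1), 0.10)
  sch <- qeeg_bands()
  others <- vapply(which(sch$band != "Alpha1"), function(b)
    band_int(sch$f_low[b], sch$f_high[b]), 0)
  expect_true(all(others < 0.05 * alpha1))
  expect_true(all(abs(rec$data[-fz, ]) < 1e-12))
})

test_that("recordings are byte-identical for identical seeds", {
  prof <- spectral_profile("normal")
  r1 <- generate_eeg(fixture_subject(), prof, duration = 10, seed = 5)
  r2 <- generate_eeg(fixture_subject(), prof, duration = 10, seed = 5)
  r3 <- generate_eeg(fixture_subject(), prof, duration = 10, seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(r1$data, r3$data))
})

test_that("generator rejects too-short durations and low sampling rates", {
  prof <- spectral_profile("normal")
  expect_error(generate_eeg(fixture_subject(), prof, duration = 4, seed = 1),
               ">= 8 s")
  expect_error(generate_eeg(fixture_subject(), prof, duration = 10, seed = 1,
                            fs = 80), "45 Hz")
})

test_that("group calibration reproduces the depression > normal beta2 ordering", {
  # Fz absolute beta2 targets: normal 1.59, depression 2.25 (profile CVs)
  profs <- list(normal = spectral_profile("normal"),
                depression = spectral_profile("depression"))
  expect_equal(profs$normal$mean["Fz", "Beta2"], 1.59)
  expect_equal(profs$depression$mean["Fz", "Beta2"], 2.25)
  realized <- lapply(c("normal", "depression"), function(g) {
    p <- quiet_profile(mean_mat = 0)
    p$mean[, "Beta2"] <- profs[[g]]$mean[, "Beta2"]
    p$cv[, "Beta2"] <- profs[[g]]$cv[, "Beta2"]
    vapply(1:50, function(i) {
      rec <- generate_eeg(fixture_subject(sprintf("%s%02d", g, i)), p,
                          duration = 16, seed = i + ifelse(g == "normal", 0, 500))
      var(rec$data[5, ])  # Fz is channel 5; total variance = beta2 power here
    }, 0)
  })
  expect_gt(mean(realized[[2]]), mean(realized[[1]]))
})

test_that("line noise and blinks load only their nominal bands/channels", {
  base <- quiet_profile(mean_mat = 1)   # flat 1 uV^2 everywhere, cv 0
  noisy <- base; noisy$line_noise_amp <- 5; noisy$line_noise_freq <- 60
  blinky <- base; blinky$blink_rate <- 20; blinky$blink_amp <- 150
  mk <- function(p) {
    rec <- generate_eeg(fixture_subject(), p, duration = 60, seed = 9, fs = 250)
    ep <- epoch_and_reject(rec, 4, 1e9)
    band_powers(compute_psd(ep))
  }
  bp0 <- mk(base); bpl <- mk(noisy); bpb <- mk(blinky)
  # 60 Hz falls outside all 8 analysis bands: band powers barely move
  expect_lt(max(abs(bpl$absolute - bp0$absolute) / bp0$absolute), 0.15)
  # blinks load frontal delta strongly, leave posterior alpha alone
  expect_gt(bpb$absolute["Fp1", "Delta"], 3 * bp0$absolute["Fp1", "Delta"])
  expect_lt(abs(bpb$absolute["O1", "Alpha1"] - bp0$absolute["O1", "Alpha1"]) /
              bp0$absolute["O1", "Alpha1"], 0.15)
})

test_that("normative generators encode the configured age trend (OLS oracle)", {
  trend <- norm_trend_config()
  tab <- generate_normative_powers(400, trend, seed = 3)
  expect_equal(nrow(tab), 400)
  expect_setequal(unique(tab$sex), c("M", "F"))
  for (cell in c("Abs_Delta_Fz", "Abs_Beta2_O1")) {
    band <- strsplit(cell, "_")[[1]][2]
    fit <- lm(log10(tab[[cell]]) ~ tab$age + factor(tab$sex))
    b <- unname(coef(fit)[2])
    expect_lt(abs(b - trend$slopes[[band]]), 0.2 * abs(trend$slopes[[band]]))
  }
  expect_equal(nrow(generate_normative_powers(0, trend, 1)), 0)
})

test_that("normative EEG cohort pairs subjects with recordings", {
  trend <- norm_trend_config()
  expect_warning(nc <- generate_normative_cohort(4, trend, seed = 2,
                                                 duration = 10),
                 "below the recommended minimum")
  expect_equal(length(nc$recordings), 4)
  expect_s3_class(nc$recordings[[1]], "eeg_recording")
  expect_equal(nc$subjects$group, rep("normative", 4))
  empty <- generate_normative_cohort(0, trend, 1)
  expect_equal(nrow(empty$subjects), 0)
  expect_length(empty$recordings, 0)
})
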