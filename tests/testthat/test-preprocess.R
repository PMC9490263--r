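test_that("1 Hz high-pass removes DC offsets", {
  data <- matrix(50, 19, 2500)                    # constant 50 uV
  rec <- matrix_recording(data)
  out <- bandpass_notch(rec)
  expect_lt(mean(abs(out$data)), 0.5)
})

test_that("notch attenuates 60 Hz by >= 20 dB and passband holds 10 Hz", {
  fs <- 250; t <- (0:(20 * fs - 1)) / fs
  tone60 <- matrix(rep(sin(2 * pi * 60 * t), 19), 19, byrow = TRUE)
  tone10 <- matrix(rep(sin(2 * pi * 10 * t), 19), 19, byrow = TRUE)
  # oracle: cascaded magnitude response at 60 Hz (notch^2 for filtfilt x FIR)
  co <- qeegscreen:::notch_coefficients(fs, 60)
  H <- function(b, a, f) {
    z <- exp(-2i * pi * f / fs)
    (b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2)
  }
  h <- qeegscreen:::fir_bandpass_taps(fs, 1, 45)
  Hfir <- function(f) sum(h * exp(-2i * pi * f / fs * seq_along(h)))
  gain60 <- Mod(H(co$b, co$a, 60))^2 * Mod(Hfir(60))
  expect_lt(20 * log10(gain60), -20)
  out60 <- bandpass_notch(matrix_recording(tone60))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(20 * log10(rms(out60$data[1, ]) / rms(tone60[1, ])), -20)
  out10 <- bandpass_notch(matrix_recording(tone10))
  expect_lt(abs(rms(out10$data[1, ]) / rms(tone10[1, ]) - 1), 0.05)
})

test_that("filtering is idempotent on in-band content and rejects bad cutoffs", {
  # in-band fixture (2-40 Hz): repeated filtering must not erode it. Signals
  # with energy exactly at the 1/45 Hz edges sit inside the FIR transition
  # band, where any finite filter keeps attenuating; those are bounded
  # separately below.
  prof <- quiet_profile(mean_mat = 0)
  prof$mean[, c("Theta", "Alpha1", "Alpha2", "Beta1", "Beta2")] <- 1
  rec <- generate_eeg(fixture_subject(), prof, duration = 60, seed = 61)
  once <- bandpass_notch(rec)
  twice <- bandpass_notch(once)
  rel <- sqrt(mean((twice$data - once$data)^2)) / sqrt(mean(once$data^2))
  expect_lt(rel, 0.01)
  # full-spectrum synthetic EEG (delta starts exactly at the 1 Hz edge)
  full <- generate_eeg(fixture_subject(), spectral_profile("normal"),
                       duration = 20, seed = 62)
  o2 <- bandpass_notch(full); t2 <- bandpass_notch(o2)
  rel2 <- sqrt(mean((t2$data - o2$data)^2)) / sqrt(mean(o2$data^2))
  expect_lt(rel2, 0.05)
  expect_error(bandpass_notch(rec, high = 130), "Nyquist")
  expect_error(bandpass_notch(rec, low = 40, high = 30), "low < high")
})

test_that("common average reference zeroes the channel mean", {
  rec2 <- matrix_recording(matrix(c(1, 3), 2, 10))
  out2 <- rereference_car(rec2)
  expect_equal(unname(out2$data[, 1]), c(-1, 1))
  set.seed(2)
  rec <- matrix_recording(matrix(rnorm(19 * 1000), 19))
  out <- rereference_car(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # idempotence on already-zero-mean input
  again <- rereference_car(out)
  expect_equal(again$data, out$data)
  expect_error(rereference_car(matrix_recording(matrix(1, 1, 10))),
               "2 channels")
})

test_that("epoching counts, rejection and errors behave as specified", {
  rec <- matrix_recording(matrix(0, 19, 300 * 250))
  ep <- epoch_and_reject(rec, 4, 100)
  expect_length(ep$epochs, 75)
  expect_true(all(ep$retained))            # all-zero: everything retained
  # planted 500 uV spike in epoch 3 only
  data <- matrix(rnorm(19 * 10 * 1000, sd = 5), 19)
  data[4, 2500] <- 500
  ep2 <- epoch_and_reject(matrix_recording(data), 4, 100)
  expect_false(ep2$retained[3])
  expect_true(all(ep2$retained[-3]))
  expect_error(epoch_and_reject(matrix_recording(matrix(0, 19, 100)), 4, 100),
               "shorter than one epoch")
  expect_error(epoch_and_reject(rec, 4, -1), "amp_threshold")
  expect_error(epoch_and_reject(rec, 0.0003, 100), "integer")
})

test_that("cleaning log proves the fixed pipeline order with parameters", {
  prof <- spectral_profile("normal", blink_rate = 6)
  rec <- generate_eeg(fixture_subject(), prof, duration = 16, seed = 3)
  ep <- preprocess_recording(rec, seed = 4)
  log <- attr(ep, "cleaning_log")
  expect_identical(vapply(log, `[[`, "", "step"),
                   c("bandpass_notch", "car", "epoch_and_reject", "ica_clean"))
  expect_equal(log[[1]]$low, 1)
  expect_equal(log[[1]]$high, 45)
  expect_equal(log[[3]]$epoch_length, 4)
  # CAR invariant still holds after ICA (linear reconstruction)
  X <- do.call(cbind, ep$epochs[ep$retained])
  expect_lt(max(abs(colMeans(X))), 1e-6)
})
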