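# Preprocessing chain: notch -> 1-45 Hz band-pass -> common average
# reference -> fixed-length epoching with amplitude-based bad-epoch
# rejection -> ICA-based artifact component removal. The order is fixed and
# every step appends to the recording's cleaning log.

append_log <- function(x, step, params) {
  log <- attr(x, "cleaning_log") %||% list()
  log[[length(log) + 1]] <- c(list(step = step), params)
  attr(x, "cleaning_log") <- log
  x
}

# --- linear-phase FIR band-pass (Hamming-windowed sinc) ------------------

fir_bandpass_taps <- function(fs, low, high, transition = 0.5) {
  n_taps <- ceiling(3.3 * fs / transition)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  k <- seq(-m, m)
  sinc <- function(fc) ifelse(k == 0, 2 * fc / fs,
                              sin(2 * pi * fc * k / fs) / (pi * k))
  h <- sinc(high) - sinc(low)
  w <- 0.54 + 0.46 * cos(pi * k / m)     # Hamming
  h * w
}

# Zero-phase FIR by symmetric taps + reflection padding, FFT convolution.
fir_apply <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad_l <- 2 * x[1] - x[pmin(m + 1, n):2]
  if (length(pad_l) < m) pad_l <- c(rep(pad_l[1], m - length(pad_l)), pad_l)
  pad_r <- 2 * x[n] - x[(n - 1):pmax(n - m, 1)]
  if (length(pad_r) < m) pad_r <- c(pad_r, rep(pad_r[length(pad_r)], m - length(pad_r)))
  xp <- c(pad_l, x, pad_r)
  nfft <- stats::nextn(length(xp) + length(h) - 1, c(2, 3, 5))
  y <- Re(fft(fft(c(xp, rep(0, nfft - length(xp)))) *
                fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[(2 * m + 1):(2 * m + n)]
}

# --- second-order IIR notch (RBJ biquad), applied forward-backward -------

notch_coefficients <- function(fs, f0, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

iir2 <- function(x, b, a) {
  ma <- stats::filter(c(0, 0, x), filter = b, method = "convolution",
                      sides = 1)[-(1:2)]
  as.numeric(stats::filter(ma, -a[2:3], method = "recursive"))
}

filtfilt2 <- function(x, b, a) rev(iir2(rev(iir2(x, b, a)), b, a))

#' Notch and band-pass filter a recording
#'
#' Applies a zero-phase second-order IIR notch (Q = 30, forward-backward)
#' followed by a zero-phase Hamming-windowed-sinc FIR band-pass with a
#' 0.5 Hz transition at the low edge. DC and out-of-band energy are
#' attenuated; shape and channel labels are preserved.
#'
#' @param rec an `eeg_recording`.
#' @param low,high band-pass cut-offs, Hz (defaults 1 and 45).
#' @param notch mains frequency to notch, Hz (default 60; `NA` or 0
#'   disables).
#' @param transition FIR transition width at the low edge, Hz.
#' @return Filtered `eeg_recording` with an updated cleaning log.
#' @export
bandpass_notch <- function(rec, low = 1, high = 45, notch = 60,
                           transition = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high)) stopf("need 0 < low < high")
  if (high >= nyq) stopf("high cut-off %.1f Hz is at or above Nyquist (%.1f Hz)",
                         high, nyq)
  data <- rec$data
  if (!is.na(notch) && notch > 0) {
    if (notch >= nyq) stopf("notch %.1f Hz is at or above Nyquist", notch)
    co <- notch_coefficients(rec$fs, notch)
    for (i in seq_len(nrow(data))) data[i, ] <- filtfilt2(data[i, ], co$b, co$a)
  }
  h <- fir_bandpass_taps(rec$fs, low, high, transition)
  for (i in seq_len(nrow(data))) data[i, ] <- fir_apply(data[i, ], h)
  out <- rec
  out$data <- data
  append_log(out, "bandpass_notch",
             list(low = low, high = high, notch = notch,
                  transition = transition, zero_phase = TRUE))
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at every sample.
#'
#' @param rec an `eeg_recording` with at least 2 channels.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stopf("CAR needs at least 2 channels")
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  append_log(out, "car", list(n_channels = nrow(rec$data)))
}

#' Segment a recording and reject high-amplitude epochs
#'
#' Cuts the recording into consecutive non-overlapping fixed-length epochs.
#' An epoch is rejected iff any channel's peak absolute amplitude exceeds
#' the threshold.
#'
#' @param rec an `eeg_recording`.
#' @param epoch_length epoch length, seconds (x sampling rate must be an
#'   integer; default 4).
#' @param amp_threshold rejection threshold, uV peak (default 100).
#' @return Object of class `epoched_eeg`: `epochs` (list of channel x
#'   sample matrices), `retained` (logical mask), and the cleaning log.
#' @export
epoch_and_reject <- function(rec, epoch_length = 4, amp_threshold = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (amp_threshold <= 0) stopf("amp_threshold must be > 0")
  m <- epoch_length * rec$fs
  if (abs(m - round(m)) > 1e-9) stopf("epoch_length x sampling rate must be an integer")
  m <- as.integer(round(m))
  n_ep <- floor(ncol(rec$data) / m)
  if (n_ep < 1) stopf("recording shorter than one epoch")
  epochs <- lapply(seq_len(n_ep), function(e)
    rec$data[, ((e - 1) * m + 1):(e * m), drop = FALSE])
  retained <- vapply(epochs, function(ep) max(abs(ep)) <= amp_threshold, TRUE)
  out <- structure(list(subject_id = rec$subject_id, channels = rec$channels,
                        fs = rec$fs, epoch_length = epoch_length,
                        epochs = epochs, retained = retained),
                   class = "epoched_eeg")
  attr(out, "cleaning_log") <- attr(rec, "cleaning_log")
  append_log(out, "epoch_and_reject",
             list(epoch_length = epoch_length, amp_threshold = amp_threshold,
                  n_epochs = n_ep, n_retained = sum(retained)))
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat("<epoched_eeg>", x$subject_id, "-", length(x$epochs), "x",
      x$epoch_length, "s epochs,", sum(x$retained), "retained\n")
  invisible(x)
}
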