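#' Welch power spectral density over retained epochs
#'
#' Per-channel PSD as the average of Hann-windowed per-epoch periodograms
#' (no overlap across the non-overlapping epochs), one-sided, in uV^2/Hz.
#' Frequency resolution is `1 / epoch_length`.
#'
#' @param ep an `epoched_eeg` with at least one retained epoch.
#' @return list with `freq` (Hz), `power` (channels x frequencies matrix),
#'   `epochs_used`, `channels`, `fs`; class `eeg_psd`.
#' @export
compute_psd <- function(ep) {
  stopifnot(inherits(ep, "epoched_eeg"))
  kept <- which(ep$retained)
  if (length(kept) == 0) stopf("zero retained epochs")
  m <- ncol(ep$epochs[[1]])
  fs <- ep$fs
  w <- 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))   # Hann
  norm <- fs * sum(w^2)
  n_half <- floor(m / 2) + 1
  freq <- (seq_len(n_half) - 1) * fs / m
  acc <- matrix(0, nrow(ep$epochs[[1]]), n_half)
  for (e in kept) {
    xw <- ep$epochs[[e]] * matrix(w, nrow(acc), m, byrow = TRUE)
    spec <- Mod(t(stats::mvfft(t(xw))))^2 / norm
    p <- spec[, seq_len(n_half), drop = FALSE]
    p[, 2:(n_half - 1)] <- 2 * p[, 2:(n_half - 1)]         # one-sided
    acc <- acc + p
  }
  structure(list(freq = freq, power = acc / length(kept),
                 epochs_used = length(kept), channels = ep$channels,
                 fs = fs, subject_id = ep$subject_id),
            class = "eeg_psd")
}

#' Absolute and relative band power
#'
#' Integrates the PSD over each band of the scheme using left-closed bins
#' (`f_low <= f < f_high`, the final band closed at its upper edge) so the
#' bands partition the spectrum exactly and shared edges are counted once.
#' Relative power is each band's absolute power divided by the sum of all
#' bands' absolute power for that channel.
#'
#' @param psd an `eeg_psd` from [compute_psd()].
#' @param scheme band scheme data.frame (default [qeeg_bands()]).
#' @return Object of class `band_power`: `absolute` and `relative`
#'   19 x n_bands matrices plus `epochs_used`.
#' @export
band_powers <- function(psd, scheme = qeeg_bands()) {
  stopifnot(inherits(psd, "eeg_psd"))
  validate_band_scheme(scheme)
  if (max(psd$freq) < max(scheme$f_high) - 1e-9)
    stopf("PSD frequency grid does not cover the band scheme")
  df <- psd$freq[2] - psd$freq[1]
  absolute <- sapply(seq_len(nrow(scheme)), function(b) {
    last <- b == nrow(scheme)
    sel <- psd$freq >= scheme$f_low[b] - 1e-9 &
      (if (last) psd$freq <= scheme$f_high[b] + 1e-9
       else psd$freq < scheme$f_high[b] - 1e-9)
    rowSums(psd$power[, sel, drop = FALSE]) * df
  })
  if (is.null(dim(absolute)))
    absolute <- matrix(absolute, nrow = length(psd$channels))
  dimnames(absolute) <- list(psd$channels, scheme$band)
  tot <- rowSums(absolute)
  if (any(tot <= 0))
    stopf("zero total power in channel(s): %s",
          paste(psd$channels[tot <= 0], collapse = ", "))
  structure(list(subject_id = psd$subject_id, absolute = absolute,
                 relative = absolute / tot, epochs_used = psd$epochs_used),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat("<band_power>", x$subject_id, "-", nrow(x$absolute), "channels x",
      ncol(x$absolute), "bands,", x$epochs_used, "epochs\n")
  print(round(colMeans(x$absolute), 3))
  invisible(x)
}
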