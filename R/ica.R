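# Symmetric FastICA (tanh contrast) with PCA whitening, plus the two
# explicit artifact-flagging rules used for cleaning:
#   (a) blink-like: frontal-dominant topography AND mostly sub-4 Hz energy;
#   (b) residual mains: narrow spectral peak at the line frequency.

# Deflation FastICA (tanh contrast). Gaussian directions carry no
# identifiable rotation, so components are extracted one at a time and
# extraction stops at the first direction that fails to converge: only the
# identifiable (non-Gaussian) components - the artifact candidates - are
# returned, and the Gaussian residual subspace is left untouched.
fast_ica <- function(X, seed, maxit = 200, tol = 1e-4, max_comp = Inf) {
  # X: channels x samples, already centred per channel
  cv <- tcrossprod(X) / ncol(X)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-9)
  K <- diag(1 / sqrt(eg$values[keep]), length(keep)) %*% t(eg$vectors[, keep])
  dewhiten <- eg$vectors[, keep] %*% diag(sqrt(eg$values[keep]), length(keep))
  Xw <- K %*% X                          # whitened, r x N
  r <- nrow(Xw); N <- ncol(Xw)
  W <- matrix(0, 0, r)
  iterations <- integer(0)
  with_seed(seed, {
    for (j in seq_len(min(r, max_comp))) {
      w <- rnorm(r)
      if (nrow(W)) w <- w - t(W) %*% (W %*% w)
      w <- w / sqrt(sum(w^2))
      converged <- FALSE
      for (it in seq_len(maxit)) {
        u <- drop(crossprod(Xw, w))      # N
        g <- tanh(u)
        w1 <- drop(Xw %*% g) / N - mean(1 - g^2) * w
        if (nrow(W)) w1 <- w1 - drop(t(W) %*% (W %*% w1))
        nw <- sqrt(sum(w1^2))
        if (nw < 1e-12) break            # nothing left in this direction
        w1 <- w1 / nw
        delta <- abs(abs(sum(w1 * w)) - 1)
        w <- w1
        if (delta < tol) { converged <- TRUE; break }
      }
      if (!converged) break
      if (anyNA(w)) stopf("FastICA numerical breakdown at component %d", j)
      W <- rbind(W, as.vector(w))
      iterations <- c(iterations, it)
    }
  })
  list(W = W, K = K, dewhiten = dewhiten, n_comp = nrow(W),
       iterations = iterations)
}

component_lowfreq_fraction <- function(s, fs, f_cut = 4) {
  n <- length(s)
  p <- Mod(fft(s))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(p[half & f < f_cut]) / sum(p[half])
}

component_line_ratio <- function(s, fs, f_line) {
  if (f_line >= fs / 2) return(0)
  n <- length(s)
  p <- Mod(fft(s))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  inband <- half & abs(f - f_line) <= 1
  ref <- half & abs(f - f_line) > 2 & abs(f - f_line) <= 10
  if (!any(inband) || !any(ref)) return(0)
  mean(p[inband]) / max(mean(p[ref]), 1e-12)
}

#' ICA-based artifact removal on retained epochs
#'
#' Runs a deflation FastICA decomposition on the concatenated retained
#' epochs, flags components as artifact when (a) the fraction of squared
#' topography weight on Fp1/Fp2/F7/F8 exceeds `frontal_threshold` AND the
#' sub-4 Hz spectral fraction exceeds `lowfreq_threshold` (eye blinks), or
#' (b) the spectral peak ratio at the line frequency exceeds
#' `line_ratio_threshold` (residual mains), zeroes the flagged components
#' and reconstructs the epochs. Deterministic given `seed`.
#'
#' @param ep an `epoched_eeg` (19 channels).
#' @param seed integer seed for the ICA initialisation.
#' @param frontal_threshold,lowfreq_threshold,line_ratio_threshold flagging
#'   thresholds (defaults 0.6, 0.5, 3).
#' @param line_freq mains frequency checked by rule (b), Hz.
#' @param min_epochs minimum retained epochs required (default 2).
#' @param maxit,tol per-component FastICA iteration cap and convergence
#'   tolerance. Extraction stops at the first component that fails to
#'   converge (an unidentifiable - in practice Gaussian - direction), so
#'   only identifiable components are candidates for flagging; an error is
#'   raised on numerical breakdown.
#' @return The cleaned `epoched_eeg`; the cleaning log records flagged
#'   component indices and their scores.
#' @export
ica_clean <- function(ep, seed = 1L, frontal_threshold = 0.6,
                      lowfreq_threshold = 0.5, line_ratio_threshold = 3,
                      line_freq = 60, min_epochs = 2,
                      maxit = 500, tol = 1e-4) {
  stopifnot(inherits(ep, "epoched_eeg"))
  kept <- which(ep$retained)
  if (length(kept) < min_epochs)
    stopf("need at least %d retained epochs, have %d", min_epochs, length(kept))
  X <- do.call(cbind, ep$epochs[kept])
  mu <- rowMeans(X)
  Xc <- X - mu
  # CAR (and any rank deficiency) is absorbed by the whitening step's
  # eigenvalue threshold; only identifiable components come back.
  fit <- fast_ica(Xc, seed, maxit = maxit, tol = tol)
  out <- ep
  scores <- list(); flagged <- integer(0)
  if (fit$n_comp > 0) {
    S <- fit$W %*% fit$K %*% Xc            # sources, k x N
    A <- fit$dewhiten %*% t(fit$W)         # topographies, 19 x k
    frontal <- match(frontal_channels(), ep$channels)
    scores <- lapply(seq_len(nrow(S)), function(j) {
      # energy (squared-weight) fraction: robust to the diffuse negative
      # weights that common-average referencing adds to any topography
      topo <- A[, j]^2
      list(frontal = sum(topo[frontal]) / sum(topo),
           lowfreq = component_lowfreq_fraction(S[j, ], ep$fs),
           line = component_line_ratio(S[j, ], ep$fs, line_freq))
    })
    flagged <- which(vapply(scores, function(s)
      (s$frontal > frontal_threshold && s$lowfreq > lowfreq_threshold) ||
        s$line > line_ratio_threshold, TRUE))
    if (length(flagged)) {
      Xr <- X - A[, flagged, drop = FALSE] %*% S[flagged, , drop = FALSE]
      m <- ncol(ep$epochs[[1]])
      for (k in seq_along(kept))
        out$epochs[[kept[k]]] <- Xr[, ((k - 1) * m + 1):(k * m), drop = FALSE]
    }
  }
  append_log(out, "ica_clean",
             list(seed = seed, n_components = fit$n_comp,
                  iterations = fit$iterations, flagged = flagged,
                  scores = scores,
                  thresholds = c(frontal = frontal_threshold,
                                 lowfreq = lowfreq_threshold,
                                 line_ratio = line_ratio_threshold)))
}

#' Full preprocessing chain for one recording
#'
#' filter -> common average reference -> epoch/reject -> ICA clean, in the
#' fixed pipeline order, with every step logged.
#'
#' @param rec an `eeg_recording`.
#' @param low,high,notch filter settings (see [bandpass_notch()]).
#' @param epoch_length,amp_threshold epoching settings
#'   (see [epoch_and_reject()]).
#' @param seed ICA seed.
#' @param ica run the ICA stage (default `TRUE`).
#' @param ... further arguments passed to [ica_clean()].
#' @return A cleaned `epoched_eeg`.
#' @export
preprocess_recording <- function(rec, low = 1, high = 45, notch = 60,
                                 epoch_length = 4, amp_threshold = 100,
                                 seed = 1L, ica = TRUE, ...) {
  rec <- bandpass_notch(rec, low, high, notch)
  rec <- rereference_car(rec)
  ep <- epoch_and_reject(rec, epoch_length, amp_threshold)
  if (ica) ep <- ica_clean(ep, seed = seed, line_freq = notch, ...)
  ep
}
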