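#' Standard 19-channel 10-20 montage
#'
#' Fixed electrode order used throughout the package for resting-state EEG
#' recorded with the international 10-20 system. All recordings, spectral
#' matrices and topographic summaries use exactly this order; re-ordering is
#' never permitted.
#'
#' @return Character vector of 19 electrode labels.
#' @export
qeeg_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# Frontal electrodes used by the ICA blink-flagging rule.
frontal_channels <- function() c("Fp1", "Fp2", "F7", "F8")

# Approximate 2-D scalp coordinates (unit head circle) for topographic plots.
montage_coords <- function() {
  m <- matrix(c(
    -0.26,  0.86,   0.26,  0.86,   # Fp1 Fp2
    -0.72,  0.52,  -0.40,  0.50,   0.00,  0.50,   0.40,  0.50,   0.72,  0.52, # F7 F3 Fz F4 F8
    -0.85,  0.00,  -0.45,  0.00,   0.00,  0.00,   0.45,  0.00,   0.85,  0.00, # T3 C3 Cz C4 T4
    -0.72, -0.52,  -0.40, -0.50,   0.00, -0.50,   0.40, -0.50,   0.72, -0.52, # T5 P3 Pz P4 T6
    -0.26, -0.86,   0.26, -0.86),  # O1 O2
    ncol = 2, byrow = TRUE)
  rownames(m) <- qeeg_montage()
  colnames(m) <- c("x", "y")
  m
}

#' The 8-band spectral analysis scheme
#'
#' Contiguous, non-overlapping frequency bands partitioning 1-45 Hz:
#' Delta 1-4, Theta 4-8, Alpha1 8-10, Alpha2 10-12, Beta1 12-15,
#' Beta2 15-20, Beta3 20-30 and Gamma 30-45 Hz. Band intervals are
#' half-open `[low, high)` so shared edges are counted exactly once
#' (energy at 10 Hz belongs to Alpha2, not Alpha1); the last band is
#' closed at 45 Hz.
#'
#' @return A data.frame with columns `band`, `f_low`, `f_high`.
#' @export
qeeg_bands <- function() {
  data.frame(
    band   = c("Delta", "Theta", "Alpha1", "Alpha2",
               "Beta1", "Beta2", "Beta3", "Gamma"),
    f_low  = c(1, 4, 8, 10, 12, 15, 20, 30),
    f_high = c(4, 8, 10, 12, 15, 20, 30, 45),
    stringsAsFactors = FALSE)
}

# Bands that enter the feature table (gamma is excluded as a feature but kept
# in the relative-power denominator).
feature_bands <- function() setdiff(qeeg_bands()$band, "Gamma")

validate_band_scheme <- function(scheme) {
  stopifnot(is.data.frame(scheme), all(c("band", "f_low", "f_high") %in% names(scheme)))
  if (any(scheme$f_high <= scheme$f_low)) stopf("band limits must be increasing")
  if (nrow(scheme) > 1 &&
      any(abs(scheme$f_high[-nrow(scheme)] - scheme$f_low[-1]) > 1e-9))
    stopf("bands must be contiguous and non-overlapping")
  invisible(scheme)
}

#' Canonical feature names
#'
#' Enumerates the 532 feature columns `<kind>_<band>_<channel>` for the four
#' feature kinds (`Abs`, `Rel`, `Abs_zscore`, `Rel_zscore`), the 7 non-gamma
#' bands and the 19 electrodes, in a fixed canonical order (kind-major, then
#' band, then channel).
#'
#' @return Character vector of length 532.
#' @export
qeeg_feature_names <- function() {
  kinds <- c("Abs", "Rel", "Abs_zscore", "Rel_zscore")
  out <- character(0)
  for (k in kinds)
    for (b in feature_bands())
      for (ch in qeeg_montage())
        out <- c(out, paste(k, b, ch, sep = "_"))
  out
}
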