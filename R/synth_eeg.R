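#' Age/sex trend configuration for the normative world
#'
#' Describes, per frequency band, a smooth linear trend of log10 absolute
#' band power with age, a sex offset, and a between-subject spread on the
#' log10 scale. The trend is anchored at a reference age on the normal-group
#' spectral profile, emulating a normative database in which band power
#' drifts slowly with age and differs mildly between sexes.
#'
#' Default slopes (log10 uV^2 per year) encode the familiar maturational
#' picture at desk realism: slow-wave and alpha power decline with age while
#' beta rises slightly.
#'
#' @param slopes named numeric, log10-power change per year for each of the
#'   8 bands.
#' @param sex_offset additive log10 offset for women relative to men.
#' @param sigma between-subject SD of log10 band power (constant across age).
#' @param ref_age age (years) at which the base profile applies.
#' @param profile base [spectral_profile()] (defaults to the normal group).
#' @return Object of class `norm_trend_config`.
#' @export
norm_trend_config <- function(slopes = c(Delta = -0.006, Theta = -0.005,
                                         Alpha1 = -0.003, Alpha2 = -0.003,
                                         Beta1 = 0.001, Beta2 = 0.0015,
                                         Beta3 = 0.0015, Gamma = 0.001),
                              sex_offset = 0.05, sigma = 0.30,
                              ref_age = 40,
                              profile = spectral_profile("normal")) {
  stopifnot(all(qeeg_bands()$band %in% names(slopes)), sigma > 0)
  structure(list(slopes = slopes[qeeg_bands()$band], sex_offset = sex_offset,
                 sigma = sigma, ref_age = ref_age, profile = profile),
            class = "norm_trend_config")
}

# log10 multiplier applied to the base profile mean for a subject.
trend_log10_shift <- function(trend, age, sex) {
  trend$slopes * (age - trend$ref_age) +
    if (identical(sex, "F")) trend$sex_offset else 0
}

#' Draw per-subject absolute band-power targets
#'
#' One draw per (channel, band) from a log-normal between-subject
#' distribution whose mean is the profile target (optionally shifted by the
#' age/sex trend) and whose coefficient of variation comes from the profile.
#'
#' @param subject list or single-row data.frame with `age` and `sex`.
#' @param profile a [spectral_profile()].
#' @param seed integer seed.
#' @param trend optional [norm_trend_config()]; when given, the log-normal
#'   median follows the configured age/sex trend with spread `trend$sigma`.
#' @return 19 x 8 matrix of absolute band-power targets, uV^2.
#' @export
draw_subject_powers <- function(subject, profile, seed, trend = NULL) {
  validate_profile(profile)
  m <- profile$mean
  with_seed(seed, {
    if (is.null(trend)) {
      sig <- sqrt(log(1 + profile$cv^2))
      z <- matrix(rnorm(length(m)), nrow(m), ncol(m))
      tgt <- m * exp(sig * z - sig^2 / 2)
    } else {
      shift <- trend_log10_shift(trend, subject$age, subject$sex)
      mu10 <- sweep(log10(pmax(m, 1e-12)), 2, shift, `+`)
      z <- matrix(rnorm(length(m)), nrow(m), ncol(m))
      tgt <- 10^(mu10 + trend$sigma * z)
      tgt[m == 0] <- 0
    }
    dimnames(tgt) <- dimnames(m)
    tgt
  })
}

# FFT brick-wall band-limited unit-variance noise, one column per channel.
bandlimited_noise <- function(n, n_ch, fs, f_lo, f_hi) {
  noise <- matrix(rnorm(n * n_ch), n, n_ch)
  spec <- stats::mvfft(noise)
  f <- (seq_len(n) - 1) * fs / n
  f_folded <- pmin(f, fs - f)
  keep <- f_folded >= f_lo & f_folded < f_hi
  spec[!keep, ] <- 0
  Re(stats::mvfft(spec, inverse = TRUE)) / n
}

scale_to_power <- function(x, target) {
  v <- apply(x, 2, var)
  sweep(x, 2, ifelse(v > 0, sqrt(target / v), 0), `*`)
}

# Biphasic eye-blink transient (positive then negative lobe), peak 1.
blink_template <- function(fs, width = 0.4) {
  t <- seq(0, width, by = 1 / fs)
  sin(2 * pi * t / width) * sin(pi * t / width)^2 / 0.7698 # peak-normalized
}

# Fixed decay of blink amplitude across the montage (dominant at Fp1/Fp2).
blink_topography <- function() {
  w <- stats::setNames(rep(0.03, 19), qeeg_montage())
  w[c("Fp1", "Fp2")] <- 1
  w[c("F7", "F8")] <- 0.5
  w[c("F3", "F4")] <- 0.3
  w["Fz"] <- 0.25
  w[c("C3", "C4", "Cz")] <- 0.1
  w
}

#' Synthesize a 19-channel resting EEG recording
#'
#' The signal is the sum over the 8 bands of independent band-limited
#' Gaussian noise, scaled per channel so the realized absolute band power
#' equals the per-subject target (drawn once from the profile via
#' [draw_subject_powers()]), plus an optional 1/f background, a mains
#' sinusoid, and stereotyped biphasic frontal blink transients. Channels are
#' generated independently (no imposed covariance).
#'
#' @param subject list or single-row data.frame with `subject_id`, `age`,
#'   `sex`.
#' @param profile a [spectral_profile()].
#' @param duration seconds (>= 8; default 300 as in 5-minute resting
#'   recordings).
#' @param seed integer seed; recordings are byte-identical for identical
#'   inputs.
#' @param fs sampling rate, Hz (default 250).
#' @param trend optional [norm_trend_config()] shifting the targets by
#'   age/sex.
#' @param targets optional 19 x 8 matrix overriding the drawn targets.
#' @return Object of class `eeg_recording`: list with `subject_id`,
#'   `channels`, `fs`, `duration` and the 19 x samples matrix `data` (uV).
#' @export
generate_eeg <- function(subject, profile, duration = 300, seed = 1L,
                         fs = 250, trend = NULL, targets = NULL) {
  validate_profile(profile)
  if (duration < 8) stopf("duration must be >= 8 s (2 cycles at 1 Hz and below)")
  if (fs <= 2 * 45) stopf("sampling rate must exceed twice the 45 Hz analysis limit")
  if (is.null(targets))
    targets <- draw_subject_powers(subject, profile, derive_seed(seed, 1L), trend)
  n <- round(duration * fs)
  bands <- qeeg_bands()
  ch <- qeeg_montage()
  with_seed(derive_seed(seed, 2L), {
    data <- matrix(0, n, length(ch))
    for (b in seq_len(nrow(bands))) {
      tgt <- targets[, bands$band[b]]
      if (all(tgt == 0)) next
      x <- bandlimited_noise(n, length(ch), fs, bands$f_low[b], bands$f_high[b])
      data <- data + scale_to_power(x, tgt)
    }
    if (profile$background_amp > 0 && profile$background_slope != 0) {
      noise <- matrix(rnorm(n * length(ch)), n, length(ch))
      spec <- stats::mvfft(noise)
      f <- (seq_len(n) - 1) * fs / n
      f_folded <- pmin(f, fs - f)
      shape <- ifelse(f_folded >= 0.5 & f_folded <= 45,
                      pmax(f_folded, 0.5)^(-profile$background_slope / 2), 0)
      bg <- Re(stats::mvfft(spec * shape, inverse = TRUE)) / n
      data <- data + scale_to_power(bg, rep(profile$background_amp, length(ch)))
    }
    if (profile$line_noise_amp > 0) {
      tt <- (seq_len(n) - 1) / fs
      data <- data + profile$line_noise_amp *
        sin(2 * pi * profile$line_noise_freq * tt)
    }
    if (profile$blink_rate > 0 && profile$blink_amp > 0) {
      tmpl <- blink_template(fs)
      topo <- blink_topography()
      n_blinks <- max(0L, round(profile$blink_rate * duration / 60))
      if (n_blinks > 0) {
        starts <- sort(sample.int(n - length(tmpl), n_blinks))
        amps <- profile$blink_amp * exp(rnorm(n_blinks, 0, 0.2))
        for (k in seq_len(n_blinks)) {
          idx <- starts[k] + seq_along(tmpl) - 1L
          data[idx, ] <- data[idx, ] + outer(tmpl * amps[k], topo)
        }
      }
    }
    structure(list(subject_id = subject$subject_id %||% "anon",
                   channels = ch, fs = fs, duration = n / fs,
                   data = t(data)),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", x$subject_id, "-", length(x$channels), "channels,",
      x$fs, "Hz,", x$duration, "s\n")
  invisible(x)
}

#' Generate a normative cohort of band-power draws
#'
#' Fast path for building and validating the normative model: subject
#' metadata plus per-subject absolute band-power draws taken directly from
#' the age/sex trend model (no time series synthesis). Relative powers are
#' the draws divided by the per-channel 8-band total. Ages are uniform on
#' the trend's support; sexes alternate so both are always represented.
#'
#' @param n number of normative subjects.
#' @param trend a [norm_trend_config()].
#' @param seed integer seed.
#' @param age_range sampled age support (default 4.5-81 years).
#' @return data.frame with metadata columns and `Abs_<band>_<channel>`,
#'   `Rel_<band>_<channel>` columns for all 8 bands.
#' @export
generate_normative_powers <- function(n, trend = norm_trend_config(),
                                      seed = 1L, age_range = c(4.5, 81)) {
  if (n == 0) return(empty_norm_table())
  subjects <- with_seed(seed, {
    data.frame(subject_id = sprintf("nrm%04d", seq_len(n)),
               sex = rep(c("M", "F"), length.out = n),
               age = runif(n, age_range[1], age_range[2]),
               bdi = 0L, group = "normative", stringsAsFactors = FALSE)
  })
  bands <- qeeg_bands()$band; ch <- qeeg_montage()
  abs_cols <- as.vector(outer(ch, bands, function(c, b) paste("Abs", b, c, sep = "_")))
  rel_cols <- sub("^Abs", "Rel", abs_cols)
  amat <- matrix(NA_real_, n, length(abs_cols), dimnames = list(NULL, abs_cols))
  rmat <- matrix(NA_real_, n, length(rel_cols), dimnames = list(NULL, rel_cols))
  for (i in seq_len(n)) {
    tgt <- draw_subject_powers(subjects[i, ], trend$profile,
                               derive_seed(seed, 100L + i), trend)
    rel <- tgt / rowSums(tgt)
    amat[i, ] <- as.vector(tgt)
    rmat[i, ] <- as.vector(rel)
  }
  cbind(subjects, as.data.frame(amat), as.data.frame(rmat))
}

empty_norm_table <- function() {
  data.frame(subject_id = character(0), sex = character(0), age = numeric(0),
             bdi = integer(0), group = character(0), stringsAsFactors = FALSE)
}

#' Generate a normative cohort with full EEG recordings
#'
#' As [generate_normative_powers()] but each subject receives a synthetic
#' recording from [generate_eeg()] with the profile evaluated at the
#' subject's age and sex. Intended for end-to-end runs where the normative
#' features must travel through the same preprocessing and spectral
#' estimation as the study cohort.
#'
#' @inheritParams generate_normative_powers
#' @param duration recording length in seconds.
#' @param min_n downstream fitting needs roughly this many subjects per sex;
#'   a warning is raised below it.
#' @return list with `subjects` (data.frame) and `recordings` (list of
#'   `eeg_recording`).
#' @export
generate_normative_cohort <- function(n, trend = norm_trend_config(),
                                      seed = 1L, duration = 300,
                                      age_range = c(4.5, 81), min_n = 60) {
  if (n == 0) return(list(subjects = empty_norm_table(), recordings = list()))
  if (n < min_n)
    warning(sprintf("n = %d normative subjects is below the recommended minimum %d",
                    n, min_n), call. = FALSE)
  tab <- generate_normative_powers(n, trend, seed, age_range)
  subjects <- tab[, c("subject_id", "sex", "age", "bdi", "group")]
  recordings <- lapply(seq_len(n), function(i) {
    tgt <- matrix(as.numeric(tab[i, grep("^Abs_", names(tab))]),
                  19, 8, dimnames = dimnames(trend$profile$mean))
    generate_eeg(subjects[i, ], trend$profile, duration,
                 seed = derive_seed(seed, 5000L + i), targets = tgt)
  })
  list(subjects = subjects, recordings = recordings)
}

#' Direct band-power draws for a study cohort
#'
#' Fast path mirroring [generate_normative_powers()] for the two-group
#' cohort: per-subject absolute band-power draws taken directly from the
#' group's spectral profile (log-normal between-subject variation, optional
#' age/sex trend shift), without synthesizing time series. Used for
#' statistical calibration studies where the spectral estimation stage is
#' not under test.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param profiles named list with `normal` and `depression`
#'   [spectral_profile()]s.
#' @param seed integer seed.
#' @param trend optional [norm_trend_config()]; when supplied the draws are
#'   additionally shifted by the subject's age/sex on the log10 scale while
#'   keeping each group's own profile CVs.
#' @return data.frame with metadata columns and `Abs_*`/`Rel_*` columns for
#'   all 8 bands x 19 channels.
#' @export
generate_cohort_powers <- function(cohort,
                                   profiles = list(
                                     normal = spectral_profile("normal"),
                                     depression = spectral_profile("depression")),
                                   seed = 1L, trend = NULL) {
  n <- nrow(cohort)
  bands <- qeeg_bands()$band; ch <- qeeg_montage()
  abs_cols <- as.vector(outer(ch, bands, function(c, b) paste("Abs", b, c, sep = "_")))
  rel_cols <- sub("^Abs", "Rel", abs_cols)
  amat <- matrix(NA_real_, n, length(abs_cols), dimnames = list(NULL, abs_cols))
  rmat <- matrix(NA_real_, n, length(rel_cols), dimnames = list(NULL, rel_cols))
  for (i in seq_len(n)) {
    prof <- profiles[[cohort$group[i]]]
    if (is.null(prof)) stopf("no profile for group '%s'", cohort$group[i])
    tgt <- draw_subject_powers(cohort[i, ], prof, derive_seed(seed, 300L + i))
    if (!is.null(trend))
      tgt <- tgt * matrix(10^trend_log10_shift(trend, cohort$age[i], cohort$sex[i]),
                          19, 8, byrow = TRUE)
    amat[i, ] <- as.vector(tgt)
    rmat[i, ] <- as.vector(tgt / rowSums(tgt))
  }
  cbind(cohort, as.data.frame(amat), as.data.frame(rmat))
}
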