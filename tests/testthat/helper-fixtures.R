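# Shared fixtures: silent profiles and small deterministic recordings.

# profile with no artifacts and flat unit targets (or custom matrix)
quiet_profile <- function(mean_mat = NULL, cv = 0) {
  p <- spectral_profile("normal", line_noise_amp = 0, blink_rate = 0,
                        background_amp = 0)
  if (!is.null(mean_mat)) p$mean[] <- mean_mat
  p$cv[] <- cv
  p
}

# recording built from a plain matrix (channels x samples)
matrix_recording <- function(data, fs = 250, id = "fix") {
  structure(list(subject_id = id, channels = qeeg_montage()[seq_len(nrow(data))],
                 fs = fs, duration = ncol(data) / fs, data = data),
            class = "eeg_recording")
}

# single-subject record for generator calls
fixture_subject <- function(id = "s1", sex = "F", age = 40)
  list(subject_id = id, sex = sex, age = age, bdi = 0L, group = "normal")

# small two-class table with informative + noise features
toy_table <- function(n_per = 30, p_noise = 8, effect = 2, seed = 1) {
  set.seed(seed)
  grp <- rep(c("normal", "depression"), each = n_per)
  f1 <- rnorm(2 * n_per) + ifelse(grp == "depression", effect, 0)
  noise <- matrix(rnorm(2 * n_per * p_noise), 2 * n_per)
  colnames(noise) <- paste0("noise", seq_len(p_noise))
  out <- cbind(data.frame(subject_id = sprintf("t%02d", seq_len(2 * n_per)),
                          group = grp, sex = "F", age = 40, bdi = 0,
                          f1 = f1, stringsAsFactors = FALSE),
               as.data.frame(noise))
  class(out) <- c("feature_table", "data.frame")
  out
}
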