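#' End-to-end screening pipeline on a synthetic cohort
#'
#' Runs the full chain: synthetic cohort -> synthetic 19-channel EEG ->
#' preprocessing (notch + 1-45 Hz band-pass, common average reference,
#' bad-epoch rejection, ICA artifact removal) -> Welch band powers ->
#' normative z-scoring -> 532-column feature table -> group statistics ->
#' six-ensemble intersection feature selection -> classifier sweep.
#'
#' Feature selection defaults to leakage-safe mode (importance computed on
#' the training partition only); `paper_mode = TRUE` replicates selection
#' on the whole data set instead.
#'
#' @param seed master seed; the run is fully deterministic given it.
#' @param config a [cohort_config()].
#' @param duration recording length, seconds (default 300; tests scale
#'   this down).
#' @param n_normative normative cohort size for the z-score model fit.
#' @param target_sizes feature-count ladder for the sweep.
#' @param classifiers classifier names (default all ten).
#' @param spec a [split_spec()] (its seed defaults to the master seed).
#' @param paper_mode select features on the whole data set (default
#'   `FALSE` = leakage-safe).
#' @param ica run the ICA cleaning stage (default `TRUE`).
#' @param compute_cv compute per-cell CV loss (default `TRUE`).
#' @param n_trees ensemble size for the importance models (default 100).
#' @param progress print stage progress (default `FALSE`).
#' @return Object of class `qeeg_screen`: `cohort`, `features`, `norm_model`,
#'   `group_stats`, `importance_tables`, `selections`, `report`, `settings`.
#' @export
qeeg_screen <- function(seed = 1L, config = cohort_config(), duration = 300,
                        n_normative = 400,
                        target_sizes = c(3, 7, 10, 14, 21, 28),
                        classifiers = CLASSIFIER_NAMES,
                        spec = NULL, paper_mode = FALSE, ica = TRUE,
                        compute_cv = TRUE, n_trees = 100, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  spec <- spec %||% split_spec(seed = derive_seed(seed, 11L))
  trend <- norm_trend_config()
  profiles <- list(normal = spectral_profile("normal"),
                   depression = spectral_profile("depression"))

  say("cohort generation")
  cohort <- generate_cohort(config, seed)

  say("EEG synthesis + preprocessing + spectra (%d subjects)", nrow(cohort))
  powers <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- generate_eeg(cohort[i, ], profiles[[cohort$group[i]]], duration,
                        seed = derive_seed(seed, 20000L + i), trend = trend)
    ep <- preprocess_recording(rec, seed = derive_seed(seed, 40000L + i),
                               ica = ica)
    powers[[i]] <- band_powers(compute_psd(ep))
  }

  say("normative model fit (n = %d)", n_normative)
  norm_table <- generate_normative_powers(n_normative, trend,
                                          derive_seed(seed, 7L))
  norm_model <- fit_normative_model(norm_table)

  say("feature table")
  features <- build_feature_table(cohort, powers, norm_model)

  say("group statistics")
  group_stats <- run_group_analysis(band_power_table(cohort, powers))

  say("ensemble feature selection")
  split <- split_data(features, spec)
  sel_table <- if (paper_mode) features else split$train
  Xsel <- feature_matrix(sel_table)
  ysel <- group_factor(sel_table$group)
  tables <- lapply(ENSEMBLE_VARIANTS, function(v)
    importance_table(train_importance_ensemble(
      Xsel, ysel, v, seed = derive_seed(seed, 13L), n_trees = n_trees)))
  selections <- sweep_threshold(tables, target_sizes)

  say("classifier sweep")
  report <- run_sweep(features, selections, classifiers, spec,
                      seed = derive_seed(seed, 17L),
                      compute_cv = compute_cv, split = split)

  structure(list(cohort = cohort, features = features,
                 norm_model = norm_model, group_stats = group_stats,
                 importance_tables = tables, selections = selections,
                 report = report,
                 settings = list(seed = seed, duration = duration,
                                 n_normative = n_normative,
                                 paper_mode = paper_mode, ica = ica,
                                 n_trees = n_trees,
                                 target_sizes = target_sizes)),
            class = "qeeg_screen")
}

#' @export
print.qeeg_screen <- function(x, ...) {
  cat("<qeeg_screen> seed", x$settings$seed, "-", nrow(x$features),
      "subjects,", ncol(x$features) - 5, "features\n")
  cat(sum(x$group_stats$significant), "significant group cells;",
      "selection mode:",
      if (x$settings$paper_mode) "whole-data" else "leakage-safe", "\n")
  print(x$report)
  invisible(x)
}

#' Label-permutation null for the sweep's best-cell accuracy
#'
#' Re-runs the classifier grid with permuted group labels (selection and
#' partition fixed) and records each permutation's best-cell test accuracy,
#' the null distribution against which the observed best cell is judged.
#'
#' @param features the `feature_table` used in the observed sweep.
#' @param selections the observed feature selections.
#' @param spec the observed [split_spec()].
#' @param seed base seed (one derived seed per permutation).
#' @param n_perm number of permutations (default 20).
#' @param classifiers classifier names.
#' @return numeric vector of `n_perm` best-cell accuracies (%).
#' @export
permutation_null <- function(features, selections, spec, seed = 1L,
                             n_perm = 20, classifiers = CLASSIFIER_NAMES) {
  vapply(seq_len(n_perm), function(p) {
    perm <- features
    perm$group <- with_seed(derive_seed(seed, 900L + p),
                            sample(perm$group))
    rep_p <- run_sweep(perm, selections, classifiers,
                       spec = split_spec(train_fraction = spec$train_fraction,
                                         seed = derive_seed(seed, 950L + p),
                                         stratified = spec$stratified,
                                         k_folds = spec$k_folds),
                       seed = derive_seed(seed, 970L + p),
                       compute_cv = FALSE)
    rep_p$best$accuracy
  }, 0)
}
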