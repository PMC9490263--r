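#' Assemble the 532-column feature table
#'
#' Combines raw absolute/relative band powers with their normative z-scored
#' counterparts into the subjects x features table used for selection and
#' classification: 4 kinds x 7 bands x 19 channels = 532 feature columns.
#' Gamma is excluded as a feature but remains in the relative-power
#' denominator. Metadata columns (`subject_id`, `group`, `sex`, `age`,
#' `bdi`) come first; row order follows the input cohort.
#'
#' @param cohort data.frame of subject metadata (from [generate_cohort()]).
#' @param powers either a list of `band_power` objects (one per subject, in
#'   cohort order) or a data.frame already holding `Abs_*`/`Rel_*` columns
#'   (e.g. from [generate_cohort_powers()]).
#' @param model a fitted [fit_normative_model()] used for the z-scored
#'   kinds.
#' @return data.frame of class `feature_table` with 5 metadata columns and
#'   the 532 features in canonical order.
#' @export
build_feature_table <- function(cohort, powers, model) {
  meta_cols <- c("subject_id", "group", "sex", "age", "bdi")
  stopifnot(all(meta_cols %in% names(cohort)))
  raw <- if (is.data.frame(powers)) powers else band_power_table(cohort, powers)
  feat <- qeeg_feature_names()
  raw_cells <- grep("zscore", feat, invert = TRUE, value = TRUE)
  missing_raw <- setdiff(raw_cells, names(raw))
  if (length(missing_raw))
    stopf("missing raw feature columns: %s ...", missing_raw[1])
  ztab <- zscore_table(model, cbind(cohort[meta_cols], raw[raw_cells]),
                       cells = raw_cells)
  if (anyNA(ztab))
    stopf("z-scores missing for subjects: %s",
          paste(unique(cohort$subject_id[which(rowSums(is.na(ztab)) > 0)]),
                collapse = ", "))
  out <- cbind(cohort[meta_cols], raw[raw_cells], as.data.frame(ztab))
  out <- out[, c(meta_cols, feat)]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Raw band powers of a cohort as a flat table
#'
#' Flattens a list of `band_power` objects into one row per subject with
#' `Abs_<band>_<channel>` and `Rel_<band>_<channel>` columns for all 8
#' bands (gamma included), prefixed by the cohort metadata. This is the
#' table group statistics run on.
#'
#' @param cohort subject metadata data.frame (rows aligned with `powers`).
#' @param powers list of `band_power` objects.
#' @return data.frame with metadata plus 2 x 19 x 8 power columns.
#' @export
band_power_table <- function(cohort, powers) {
  stopifnot(length(powers) == nrow(cohort))
  bands <- colnames(powers[[1]]$absolute); ch <- rownames(powers[[1]]$absolute)
  abs_cols <- as.vector(outer(ch, bands,
                              function(c, b) paste("Abs", b, c, sep = "_")))
  rel_cols <- sub("^Abs", "Rel", abs_cols)
  amat <- t(vapply(powers, function(bp) as.vector(bp$absolute),
                   numeric(length(abs_cols))))
  rmat <- t(vapply(powers, function(bp) as.vector(bp$relative),
                   numeric(length(rel_cols))))
  colnames(amat) <- abs_cols; colnames(rmat) <- rel_cols
  cbind(cohort, as.data.frame(amat), as.data.frame(rmat))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x), "subjects x", ncol(x) - 5, "features\n")
  if ("group" %in% names(x)) print(table(x$group))
  invisible(x)
}

# Feature-column matrix (no metadata) as a numeric matrix.
feature_matrix <- function(table, features = NULL) {
  features <- features %||% setdiff(names(table),
                                    c("subject_id", "group", "sex", "age", "bdi"))
  as.matrix(table[, features, drop = FALSE])
}

#' Write a feature table as CSV
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path CSV written by [write_feature_table()].
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}
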