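# Sex- and age-stratified normative model: per (sex, channel, band, kind)
# cell, a least-squares polynomial in age for the mean of the transformed
# feature (log10 for absolute power, clamped logit for relative power), with
# a constant residual-SD spread. Raw features are standardized against the
# model as z = (transform(x) - mean(age, sex)) / spread.

norm_transform <- function(values, kind) {
  if (kind == "Abs") log10(pmax(values, 1e-12))
  else stats::qlogis(pmin(pmax(values, 1e-6), 1 - 1e-6))
}

feature_kind <- function(cell) sub("_.*$", "", cell)

#' Fit the normative z-score model
#'
#' Fits, per sex and per feature cell (channel x band x kind), a polynomial
#' regression of the transformed feature on age over a normative cohort,
#' with spread taken as the SD of the residuals. A sex with fewer than
#' `min_n` subjects or an age span under `min_age_span` years has all its
#' cells marked unfit; scoring against unfit cells errors.
#'
#' @param norm_table data.frame with columns `sex`, `age` and feature
#'   columns `Abs_<band>_<channel>` / `Rel_<band>_<channel>` (e.g. from
#'   [generate_normative_powers()]).
#' @param degree polynomial degree in age (default 2).
#' @param min_n minimum subjects per sex (default 30).
#' @param min_age_span minimum age range per sex, years (default 20).
#' @return Object of class `normative_model`.
#' @export
fit_normative_model <- function(norm_table, degree = 2, min_n = 30,
                                min_age_span = 20) {
  stopifnot(all(c("sex", "age") %in% names(norm_table)))
  cells <- grep("^(Abs|Rel)_", names(norm_table), value = TRUE)
  if (!length(cells)) stopf("no Abs_/Rel_ feature columns found")
  fits <- list()
  for (sx in c("M", "F")) {
    rows <- which(norm_table$sex == sx)
    n <- length(rows)
    span <- if (n) diff(range(norm_table$age[rows])) else 0
    if (n < min_n || span < min_age_span) {
      fits[[sx]] <- list(fit = FALSE, n = n,
                         reason = if (n < min_n)
                           sprintf("n = %d < min_n = %d", n, min_n)
                         else sprintf("age span %.1f < %.1f years", span,
                                      min_age_span))
      next
    }
    age <- norm_table$age[rows]
    X <- outer(age, 0:degree, `^`)
    Y <- sapply(cells, function(cl)
      norm_transform(norm_table[[cl]][rows], feature_kind(cl)))
    fit <- lm.fit(X, Y)
    res <- as.matrix(fit$residuals)
    spread <- sqrt(colSums(res^2) / (n - (degree + 1)))
    if (any(spread <= 0)) stopf("degenerate (zero-spread) normative cell")
    co <- as.matrix(fit$coefficients)
    dimnames(co) <- list(NULL, cells)
    names(spread) <- cells
    fits[[sx]] <- list(fit = TRUE, n = n, coef = co, spread = spread,
                       age_range = range(age))
  }
  structure(list(degree = degree, cells = cells, sexes = fits,
                 transforms = c(Abs = "log10", Rel = "logit"),
                 schema_version = 1L),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model> degree", x$degree, "polynomial in age,",
      length(x$cells), "cells/sex\n")
  for (sx in names(x$sexes)) {
    s <- x$sexes[[sx]]
    if (s$fit)
      cat(sprintf("  %s: n = %d, ages %.1f-%.1f\n", sx, s$n,
                  s$age_range[1], s$age_range[2]))
    else cat(sprintf("  %s: unfit (%s)\n", sx, s$reason))
  }
  invisible(x)
}

#' @export
coef.normative_model <- function(object, sex = "F", ...) {
  s <- object$sexes[[sex]]
  if (is.null(s) || !s$fit) stopf("sex '%s' is unfit in this model", sex)
  s$coef
}

check_cell_fit <- function(model, sex, cell) {
  s <- model$sexes[[sex]]
  if (is.null(s) || !isTRUE(s$fit))
    stopf("normative cells for sex '%s' are unfit%s", sex,
          if (!is.null(s$reason)) paste0(" (", s$reason, ")") else "")
  if (!cell %in% model$cells) stopf("unknown normative cell '%s'", cell)
  lo <- s$age_range[1] - 2; hi <- s$age_range[2] + 2
  list(s = s, lo = lo, hi = hi)
}

normative_mean <- function(model, sex, cell, age) {
  s <- model$sexes[[sex]]
  drop(outer(age, 0:model$degree, `^`) %*% s$coef[, cell])
}

#' Z-score a raw feature against the normative model
#'
#' `z = (transform(value) - mean(age, sex)) / spread(sex)` on the cell's
#' transformed scale. Errors for unfit cells and for ages more than 2 years
#' outside the fitted range.
#'
#' @param value raw feature value(s) (uV^2 for `Abs`, fraction for `Rel`).
#' @param age subject age(s), years.
#' @param sex `"M"` or `"F"`.
#' @param cell feature cell name, e.g. `"Abs_Beta2_Fz"`.
#' @param model a [fit_normative_model()] fit.
#' @return Numeric z-score(s), unitless.
#' @export
zscore <- function(value, age, sex, cell, model) {
  stopifnot(inherits(model, "normative_model"))
  ck <- check_cell_fit(model, sex, cell)
  if (any(age < ck$lo | age > ck$hi))
    stopf("age outside the fitted range [%.1f, %.1f] (+/- 2 y) for sex '%s'",
          ck$s$age_range[1], ck$s$age_range[2], sex)
  (norm_transform(value, feature_kind(cell)) -
     normative_mean(model, sex, cell, age)) / ck$s$spread[[cell]]
}

# Vectorized scoring of a whole cohort table; returns a matrix of z-scores
# with `<kind>_zscore_` column names. Errors list the offending subjects.
zscore_table <- function(model, table, cells = NULL) {
  stopifnot(inherits(model, "normative_model"))
  cells <- cells %||% intersect(model$cells, names(table))
  bad_sex <- !vapply(table$sex, function(sx)
    isTRUE(model$sexes[[sx]]$fit), TRUE)
  if (any(bad_sex))
    stopf("no fitted normative cells for subjects: %s",
          paste(table$subject_id[bad_sex], collapse = ", "))
  out <- matrix(NA_real_, nrow(table), length(cells))
  colnames(out) <- sub("^(Abs|Rel)_", "\\1_zscore_", cells)
  for (sx in unique(table$sex)) {
    rows <- which(table$sex == sx)
    s <- model$sexes[[sx]]
    oob <- table$age[rows] < s$age_range[1] - 2 |
      table$age[rows] > s$age_range[2] + 2
    if (any(oob))
      stopf("age outside fitted range [%.1f, %.1f] (+/- 2 y) for subjects: %s",
            s$age_range[1], s$age_range[2],
            paste(table$subject_id[rows][oob], collapse = ", "))
    Xage <- outer(table$age[rows], 0:model$degree, `^`)
    mu <- Xage %*% s$coef[, cells, drop = FALSE]
    raw <- sapply(cells, function(cl)
      norm_transform(table[[cl]][rows], feature_kind(cl)))
    out[rows, ] <- sweep(raw - mu, 2, s$spread[cells], `/`)
  }
  out
}

#' Serialize a normative model to JSON
#'
#' @param model a `normative_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  obj <- list(schema_version = model$schema_version, degree = model$degree,
              transforms = as.list(model$transforms), cells = model$cells,
              sexes = lapply(model$sexes, function(s) {
                if (!s$fit) return(list(fit = FALSE, n = s$n, reason = s$reason))
                list(fit = TRUE, n = s$n, age_range = s$age_range,
                     coef = list(values = as.vector(s$coef),
                                 nrow = nrow(s$coef)),
                     spread = unname(s$spread))
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a normative model from JSON
#'
#' @param path JSON path written by [write_normative_model()].
#' @return A `normative_model`.
#' @export
read_normative_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- obj$cells
  sexes <- lapply(obj$sexes, function(s) {
    if (!isTRUE(s$fit)) return(list(fit = FALSE, n = s$n, reason = s$reason))
    co <- matrix(s$coef$values, nrow = s$coef$nrow)
    colnames(co) <- cells
    list(fit = TRUE, n = s$n, coef = co,
         spread = stats::setNames(s$spread, cells), age_range = s$age_range)
  })
  structure(list(degree = obj$degree, cells = cells, sexes = sexes,
                 transforms = unlist(obj$transforms),
                 schema_version = obj$schema_version),
            class = "normative_model")
}
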