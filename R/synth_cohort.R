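#' Cohort configuration
#'
#' Demographic targets for the synthetic two-group cohort. Defaults reproduce
#' the reference study's groups: 116 potential-depression subjects
#' (23 men, 95 women, age 58.66 +/- 15.08 years, BDI 21.17 +/- 6.28, all
#' above the 14.48 BDI cut-off) and 80 normal controls (44 men, 36 women,
#' age 48.66 +/- 16.71 years, BDI 0).
#'
#' @param n_depression,n_normal group sizes.
#' @param dep_male,normal_male exact male counts per group.
#' @param dep_age_mean,dep_age_sd,normal_age_mean,normal_age_sd age moments
#'   (years) of the truncated normal draws; support is `age_range`.
#' @param dep_bdi_mean,dep_bdi_sd BDI moments for the depression group
#'   (truncated below at `bdi_cutoff`, rounded to integers).
#' @param bdi_cutoff BDI screening cut-off (default 14.48).
#' @param age_range support of the age distribution (years; the normative
#'   model's fitted range).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_depression = 116, n_normal = 80,
                          dep_male = 23, normal_male = 44,
                          dep_age_mean = 58.66, dep_age_sd = 15.08,
                          normal_age_mean = 48.66, normal_age_sd = 16.71,
                          dep_bdi_mean = 21.17, dep_bdi_sd = 6.28,
                          bdi_cutoff = 14.48,
                          age_range = c(4.5, 81)) {
  if (n_depression == 0) dep_male <- 0       # empty group: no sex split
  if (n_normal == 0) normal_male <- 0
  cfg <- list(n_depression = n_depression, n_normal = n_normal,
              dep_male = dep_male, normal_male = normal_male,
              dep_age_mean = dep_age_mean, dep_age_sd = dep_age_sd,
              normal_age_mean = normal_age_mean, normal_age_sd = normal_age_sd,
              dep_bdi_mean = dep_bdi_mean, dep_bdi_sd = dep_bdi_sd,
              bdi_cutoff = bdi_cutoff, age_range = age_range)
  if (n_depression < 0 || n_normal < 0) stopf("group sizes must be >= 0")
  if (dep_male > n_depression || normal_male > n_normal ||
      dep_male < 0 || normal_male < 0)
    stopf("sex counts must lie within the group size")
  structure(cfg, class = "cohort_config")
}

# Inverse-CDF truncated normal draw on [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic two-group cohort
#'
#' Draws subject metadata deterministically from a [cohort_config()]: sex
#' counts are exact (not sampled); ages come from truncated normals on the
#' configured support; depression BDI scores come from a truncated normal
#' above the cut-off (rounded to integers) and controls have BDI 0.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical `(config, seed)` give identical
#'   cohorts.
#' @return data.frame with columns `subject_id`, `sex`, `age`, `bdi`,
#'   `group`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    lo <- config$age_range[1]; hi <- config$age_range[2]
    one_group <- function(n, n_male, group, age_mean, age_sd, prefix) {
      if (n == 0)
        return(data.frame(subject_id = character(0), sex = character(0),
                          age = numeric(0), bdi = integer(0),
                          group = character(0), stringsAsFactors = FALSE))
      sex <- c(rep("M", n_male), rep("F", n - n_male))
      age <- rtruncnorm(n, age_mean, age_sd, lo, hi)
      if (group == "depression") {
        bdi <- as.integer(round(rtruncnorm(n, config$dep_bdi_mean,
                                           config$dep_bdi_sd,
                                           config$bdi_cutoff, 63)))
        bdi <- pmax(bdi, as.integer(ceiling(config$bdi_cutoff)))
      } else bdi <- rep(0L, n)
      data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
                 sex = sex, age = age, bdi = bdi, group = group,
                 stringsAsFactors = FALSE)
    }
    dep <- one_group(config$n_depression, config$dep_male, "depression",
                     config$dep_age_mean, config$dep_age_sd, "dep")
    nor <- one_group(config$n_normal, config$normal_male, "normal",
                     config$normal_age_mean, config$normal_age_sd, "ctl")
    rbind(dep, nor)
  })
}
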