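#' @useDynLib qeegscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif fft var sd median coef lm.fit qnorm pnorm
#'   shapiro.test t.test wilcox.test quantile predict aggregate
NULL

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb (nor
# depend on) the global RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
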