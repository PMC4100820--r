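# Internal helpers shared across modules.

# Geometric mean; any zero drives the result to 0 (exp(-Inf)).
geo_mean <- function(x) {
  exp(mean(log(x)))
}

# Evaluate `fun()` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, fun) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("configuration error: 'seed' must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fun()
}

# Truncated-normal draws (left truncation at 0) via inverse-CDF sampling, so
# the output has no point mass at zero and stays reproducible under set.seed.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  stats::qnorm(stats::runif(n, min = lo, max = 1), mean = mean, sd = sd)
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
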