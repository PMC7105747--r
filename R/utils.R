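# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that seeded generators never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Standard error of the mean; n = 1 yields 0 with a warning rather than NA
# so single-cell curves can still be plotted and propagated.
sem <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n == 1) {
    warning("SEM of a single observation is reported as 0", call. = FALSE)
    return(0)
  }
  stats::sd(x) / sqrt(n)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Log-normal draws parameterised by arithmetic mean and sd (both on the
# natural scale); sd = 0 degenerates to the constant mean.
rlnorm_mean_sd <- function(n, mean, sd) {
  if (mean < 0) stopf("log-normal mean must be >= 0, got %g", mean)
  if (sd < 0) stopf("log-normal sd must be >= 0, got %g", sd)
  if (mean == 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# Boltzmann activation curve, the workhorse sigmoid of this package.
boltzmann <- function(v, v_half, k) 1 / (1 + exp(-(v - v_half) / k))
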