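#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves going up, the convention
#' used when tabulating calibration bounds in whole millions of years.
#' (Base R's `round()` rounds halves to even.)
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Numerically stable log-sum-exp
#' @param x numeric vector of log values.
#' @return log(sum(exp(x))).
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Mean of a lognormal distribution
#'
#' Used to express relaxed-clock rate hyperpriors on the natural scale:
#' if `m ~ Lognormal(mu, sigma)` the prior mean rate is
#' `exp(mu + sigma^2 / 2)` (changes per character per time unit).
#'
#' @param meanlog,sdlog parameters of the lognormal on the log scale.
#' @return the distribution mean.
#' @export
lognormal_mean <- function(meanlog, sdlog) exp(meanlog + sdlog^2 / 2)

#' Retained MCMC sample count
#'
#' Bookkeeping for pooled posterior samples: `runs` independent chains of
#' `iterations` generations sampled every `interval`, with a fraction
#' `burnin` of each chain's samples discarded before pooling.
#'
#' @param runs number of independent chains.
#' @param iterations generations per chain.
#' @param interval sampling interval (iterations must be divisible by it).
#' @param burnin fraction in `[0, 1)` discarded per chain.
#' @return total retained sample count across chains.
#' @export
mcmc_retained_samples <- function(runs, iterations, interval, burnin = 0.1) {
  stopifnot(runs >= 1, burnin >= 0, burnin < 1)
  if (iterations %% interval != 0)
    stop("iterations must be divisible by the sampling interval")
  per_run <- iterations / interval
  runs * per_run * (1 - burnin)
}

# Derive a stream of sub-seeds from one master seed, keeping each below
# 2^31 so they remain valid R integers.
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1)
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(as.integer(master %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
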