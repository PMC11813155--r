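# MCMC convergence checks used in place of visual trace-plot inspection:
# effective sample size (initial-positive-sequence estimator) and a Geweke
# mean-difference z-score with AR-spectrum variance estimates.

#' Effective sample size of an MCMC draw sequence
#'
#' Autocorrelation-adjusted sample size using Geyer's initial positive
#' sequence truncation of the autocovariance sum.
#'
#' @param x Numeric vector of retained draws.
#' @return Estimated effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(n)
  rho <- drop(stats::acf(x, lag.max = min(n - 2L, 500L),
                         plot = FALSE)$acf)[-1]
  npair <- floor(length(rho) / 2)
  tau <- 1
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g <= 0) break
    tau <- tau + 2 * g
  }
  min(n, n / tau)
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`, standardized by AR-model spectral-density-at-zero variance
#' estimates for each window.
#'
#' @param x Numeric vector of retained draws.
#' @param frac1,frac2 Window fractions (defaults 0.1 and 0.5).
#' @return z-score (0 for constant chains).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  if (stats::sd(x) == 0) return(0)
  s0 <- function(z) {
    if (length(z) < 8L || stats::sd(z) == 0) return(stats::var(z))
    fit <- try(stats::ar(z, aic = TRUE,
                         order.max = min(10L, length(z) - 2L)), silent = TRUE)
    if (inherits(fit, "try-error") || length(fit$ar) == 0L)
      return(stats::var(z))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  (mean(a) - mean(b)) / sqrt(s0(a) / length(a) + s0(b) / length(b))
}

# Diagnose the variance-component draws of a sampler. Returns a data.frame
# and warns (never errors) when a chain looks unconverged.
diagnose_draws <- function(draws, ess_min = 100, z_max = 3) {
  params <- colnames(draws)
  d <- data.frame(parameter = params,
                  ess = vapply(params, function(p) ess(draws[, p]), 0),
                  geweke_z = vapply(params, function(p) geweke_z(draws[, p]), 0))
  d$ok <- d$ess >= ess_min & abs(d$geweke_z) <= z_max
  if (!all(d$ok))
    warning(sprintf("MCMC diagnostics flagged: %s",
                    paste(d$parameter[!d$ok], collapse = ", ")))
  d
}
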