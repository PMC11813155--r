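#' Calibrate hyperprior scales from a target proportion of variance explained
#'
#' Translates a target proportion of phenotypic variance explained by the
#' predictors (`R2`, default 0.8, chosen to match the broad-sense
#' heritability of line means) into concrete scaled-inverse-chi-square prior
#' scales. The residual scale is set so the prior mode equals
#' `(1 - R2) * Var(y)`. Each variance component receives a share
#' `weights[i] * R2 * Var(y)` of prior variance explained: for an
#' effects-type component (spike-and-slab coefficients) the slab-variance
#' mode is that share divided by `pi * sum_j Var(x_j)`; for a kernel
#' component the mode is the share divided by `mean(diag(T))`.
#'
#' @param y Numeric response (trait line means).
#' @param components List of component descriptors; each is a list with
#'   `type = "effects"` (fields `msx` = sum of predictor column variances,
#'   `pi` = prior inclusion probability) or `type = "kernel"` (field
#'   `mean_diag`).
#' @param R2 Target proportion of variance explained, in (0, 1).
#' @param weights Per-component shares summing to 1; default equal.
#' @param df_effects,df_residual Scaled-inverse-chi-square degrees of
#'   freedom (default 5 each).
#' @return List with `residual = list(df, S, mode)` and `components`, a
#'   list of `list(df, S, mode)` in input order.
#' @export
calibrate_priors <- function(y, components, R2 = 0.8, weights = NULL,
                             df_effects = 5, df_residual = 5) {
  if (R2 <= 0 || R2 >= 1) stop("R2 must lie in (0, 1)")
  vy <- stats::var(as.numeric(y))
  if (!is.finite(vy) || vy <= 0) stop("response has no variance")
  k <- length(components)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  res_mode <- (1 - R2) * vy
  out_comp <- vector("list", k)
  for (i in seq_len(k)) {
    comp <- components[[i]]
    share <- weights[i] * R2 * vy
    mode <- switch(comp$type,
      effects = {
        if (comp$msx <= 0) stop("msx must be positive")
        share / (comp$pi * comp$msx)
      },
      kernel = {
        if (comp$mean_diag <= 0) stop("mean_diag must be positive")
        share / comp$mean_diag
      },
      stop("unknown component type"))
    out_comp[[i]] <- list(df = df_effects,
                          S = mode * (df_effects + 2) / df_effects,
                          mode = mode, prior_ve = share)
  }
  list(residual = list(df = df_residual,
                       S = res_mode * (df_residual + 2) / df_residual,
                       mode = res_mode),
       components = out_comp)
}
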