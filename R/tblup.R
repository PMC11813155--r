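# Eigen-factorization of a training kernel block with PSD clipping. Small
# (or slightly negative) eigenvalues below 1e-8 * trace/n are treated as
# zero, the conditioning safeguard for rank-deficient kernels.
kernel_eigen <- function(Tt) {
  eg <- eigen(Tt, symmetric = TRUE)
  thr <- 1e-8 * sum(diag(Tt)) / nrow(Tt)
  d <- eg$values
  d[d < thr] <- 0
  list(U = eg$vectors, d = d, pos = d > 0)
}

# Draw the rotated random-effect coefficients a | rest for one kernel:
# independent Gaussians in the eigenbasis.
draw_rotated <- function(zstar, d, st2, se2) {
  a <- numeric(length(zstar))
  pos <- d > 0
  if (st2 > 0 && any(pos)) {
    dn <- d[pos] * st2 + se2
    mn <- d[pos] * st2 * zstar[pos] / dn
    vr <- d[pos] * st2 * se2 / dn
    a[pos] <- mn + sqrt(vr) * rnorm(sum(pos))
  }
  a
}

#' Transcriptomic BLUP (kernel mixed model) by Gibbs sampling
#'
#' Fits `y = t + e` with `t ~ N(0, T sigma_t2)` on the training lines,
#' sampling `t` and the two variance components from their Gaussian /
#' scaled-inverse-chi-square conditionals in the eigenbasis of the training
#' kernel. Test-line effects are predicted by the conditional expectation
#' given the training effects under the joint kernel (cross-block of `T`).
#' Default schedule: 85000 iterations, 10000 burn-in, thin 50.
#'
#' @param T Full `n x n` kernel over all lines ([build_trm()]).
#' @param y Centered response for the training lines (length =
#'   `length(train)`).
#' @param train,test Integer indices into the rows of `T`; `test` may be
#'   empty.
#' @param n_iter,burn_in,thin MCMC schedule.
#' @param R2 Target proportion of variance explained for prior calibration.
#' @param df Scaled-inverse-chi-square degrees of freedom.
#' @param fixed Named list fixing `sigma_t2` and/or `sigma_e2`.
#' @param seed Integer seed.
#' @param warn Emit convergence-diagnostic warnings.
#' @return Object of class `tblup_fit`: `predictions` (test lines, centered
#'   scale), `t_train`, `variance_draws`, `var_means`, `retained_draws`,
#'   `diagnostics`, `failed`.
#' @export
fit_tblup <- function(T, y, train = seq_len(nrow(T)), test = integer(0),
                      n_iter = 85000L, burn_in = 10000L, thin = 50L,
                      R2 = 0.8, df = 5, fixed = list(), seed = 1L,
                      warn = TRUE) {
  T <- unclass(as.matrix(T))
  y <- as.numeric(y)
  stopifnot(length(y) == length(train))
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L || (n_iter - burn_in) %% thin != 0L)
    stop("(n_iter - burn_in) must be a multiple of thin")
  Tt <- T[train, train, drop = FALSE]
  ke <- kernel_eigen(Tt)
  n <- length(y)
  zstar <- drop(crossprod(ke$U, y))
  calib <- calibrate_priors(y, list(list(type = "kernel",
                                         mean_diag = mean(diag(Tt)))),
                            R2 = R2, weights = 1,
                            df_effects = df, df_residual = df)
  update_st <- is.null(fixed$sigma_t2)
  update_se <- is.null(fixed$sigma_e2)
  st2 <- if (update_st) calib$components[[1]]$mode else fixed$sigma_t2
  se2 <- if (update_se) calib$residual$mode else fixed$sigma_e2
  St <- calib$components[[1]]$S; Se <- calib$residual$S
  n_ret <- (n_iter - burn_in) %/% thin
  a_sum <- numeric(n)
  draws <- matrix(0, n_ret, 2, dimnames = list(NULL, c("sigma_t2", "sigma_e2")))
  ret <- 0L
  set.seed(seed)
  rpos <- sum(ke$pos)
  for (it in seq_len(n_iter)) {
    a <- draw_rotated(zstar, ke$d, st2, se2)
    if (update_st) {
      qa <- if (rpos) sum(a[ke$pos]^2 / ke$d[ke$pos]) else 0
      st2 <- (qa + df * St) / rchisq(1L, df + rpos)
    }
    if (update_se)
      se2 <- (sum((zstar - a)^2) + df * Se) / rchisq(1L, df + n)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      ret <- ret + 1L
      a_sum <- a_sum + a
      draws[ret, ] <- c(st2, se2)
    }
  }
  abar <- a_sum / ret
  t_train <- drop(ke$U %*% abar)
  predictions <- numeric(length(test))
  if (length(test)) {
    dinv <- ifelse(ke$pos, 1 / pmax(ke$d, .Machine$double.eps), 0)
    alpha <- drop(ke$U %*% (abar * dinv))
    predictions <- drop(T[test, train, drop = FALSE] %*% alpha)
  }
  diags <- if (warn) diagnose_draws(draws)
           else suppressWarnings(diagnose_draws(draws))
  structure(list(predictions = predictions, t_train = t_train,
                 variance_draws = draws, var_means = colMeans(draws),
                 retained_draws = ret,
                 schedule = c(n_iter = n_iter, burn_in = burn_in, thin = thin),
                 diagnostics = diags, failed = FALSE,
                 failure_cause = NA_character_),
            class = "tblup_fit")
}

#' Two-kernel transcriptomic BLUP partitioned by a gene set (GO-TBLUP)
#'
#' Fits `y = t_GO + t_notGO + e` with independent kernel random effects for
#' the genes inside and outside the selected term. Both variance components
#' are sampled; predictions sum the two conditional means; the posterior
#' mean share `sigma_tGO2 / (sigma_tGO2 + sigma_tnotGO2)` is reported. Both
#' gene blocks must be nonempty - a term covering the whole universe must
#' be fitted with [fit_tblup()] instead.
#'
#' @param T_go,T_not Full kernels for the in-term and out-of-term gene
#'   blocks ([build_trm()] on the corresponding columns; both carry a
#'   positive `scale_m`).
#' @inheritParams fit_tblup
#' @param weights Length-2 shares of target variance explained (default
#'   0.5/0.5).
#' @param fixed Named list fixing `sigma_go2`, `sigma_not2`, `sigma_e2`.
#' @return Object of class `go_tblup_fit`; as `tblup_fit` plus
#'   `go_share` (posterior mean GO variance share) and per-kernel effects.
#' @export
fit_go_tblup <- function(T_go, T_not, y, train = seq_len(nrow(T_go)),
                         test = integer(0), weights = c(0.5, 0.5),
                         n_iter = 85000L, burn_in = 10000L, thin = 50L,
                         R2 = 0.8, df = 5, fixed = list(), seed = 1L,
                         warn = TRUE) {
  m_go <- attr(T_go, "scale_m"); m_not <- attr(T_not, "scale_m")
  if (is.null(m_go) || is.null(m_not) || m_go == 0L || m_not == 0L)
    stop("both gene blocks must be nonempty; use fit_tblup for a single block")
  T_go <- unclass(as.matrix(T_go)); T_not <- unclass(as.matrix(T_not))
  y <- as.numeric(y)
  stopifnot(length(y) == length(train))
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L || (n_iter - burn_in) %% thin != 0L)
    stop("(n_iter - burn_in) must be a multiple of thin")
  T1 <- T_go[train, train, drop = FALSE]
  T2 <- T_not[train, train, drop = FALSE]
  k1 <- kernel_eigen(T1); k2 <- kernel_eigen(T2)
  n <- length(y)
  calib <- calibrate_priors(y,
    list(list(type = "kernel", mean_diag = mean(diag(T1))),
         list(type = "kernel", mean_diag = mean(diag(T2)))),
    R2 = R2, weights = weights, df_effects = df, df_residual = df)
  up1 <- is.null(fixed$sigma_go2); up2 <- is.null(fixed$sigma_not2)
  upe <- is.null(fixed$sigma_e2)
  s1 <- if (up1) calib$components[[1]]$mode else fixed$sigma_go2
  s2 <- if (up2) calib$components[[2]]$mode else fixed$sigma_not2
  se2 <- if (upe) calib$residual$mode else fixed$sigma_e2
  S1 <- calib$components[[1]]$S; S2 <- calib$components[[2]]$S
  Se <- calib$residual$S
  n_ret <- (n_iter - burn_in) %/% thin
  t1 <- numeric(n); t2 <- numeric(n)
  a1_sum <- numeric(n); a2_sum <- numeric(n)
  draws <- matrix(0, n_ret, 4,
                  dimnames = list(NULL, c("sigma_go2", "sigma_not2",
                                          "sigma_e2", "go_share")))
  ret <- 0L
  set.seed(seed)
  r1 <- sum(k1$pos); r2 <- sum(k2$pos)
  for (it in seq_len(n_iter)) {
    z1 <- drop(crossprod(k1$U, y - t2))
    a1 <- draw_rotated(z1, k1$d, s1, se2)
    t1 <- drop(k1$U %*% a1)
    z2 <- drop(crossprod(k2$U, y - t1))
    a2 <- draw_rotated(z2, k2$d, s2, se2)
    t2 <- drop(k2$U %*% a2)
    if (up1) {
      qa <- if (r1) sum(a1[k1$pos]^2 / k1$d[k1$pos]) else 0
      s1 <- (qa + df * S1) / rchisq(1L, df + r1)
    }
    if (up2) {
      qa <- if (r2) sum(a2[k2$pos]^2 / k2$d[k2$pos]) else 0
      s2 <- (qa + df * S2) / rchisq(1L, df + r2)
    }
    if (upe) {
      resid <- y - t1 - t2
      se2 <- (sum(resid^2) + df * Se) / rchisq(1L, df + n)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      ret <- ret + 1L
      a1_sum <- a1_sum + a1; a2_sum <- a2_sum + a2
      draws[ret, ] <- c(s1, s2, se2, s1 / (s1 + s2))
    }
  }
  a1bar <- a1_sum / ret; a2bar <- a2_sum / ret
  predictions <- numeric(length(test))
  if (length(test)) {
    d1inv <- ifelse(k1$pos, 1 / pmax(k1$d, .Machine$double.eps), 0)
    d2inv <- ifelse(k2$pos, 1 / pmax(k2$d, .Machine$double.eps), 0)
    predictions <-
      drop(T_go[test, train, drop = FALSE] %*% (k1$U %*% (a1bar * d1inv))) +
      drop(T_not[test, train, drop = FALSE] %*% (k2$U %*% (a2bar * d2inv)))
  }
  dcols <- c("sigma_go2", "sigma_not2", "sigma_e2")
  diags <- if (warn) diagnose_draws(draws[, dcols, drop = FALSE])
           else suppressWarnings(diagnose_draws(draws[, dcols, drop = FALSE]))
  structure(list(predictions = predictions,
                 t_go = drop(k1$U %*% a1bar), t_not = drop(k2$U %*% a2bar),
                 variance_draws = draws, var_means = colMeans(draws),
                 go_share = mean(draws[, "go_share"]),
                 retained_draws = ret,
                 schedule = c(n_iter = n_iter, burn_in = burn_in, thin = thin),
                 diagnostics = diags, failed = FALSE,
                 failure_cause = NA_character_),
            class = "go_tblup_fit")
}

#' Partition a standardized expression matrix into GO / non-GO kernels
#'
#' Builds the two block kernels for [fit_go_tblup()] from one standardized
#' matrix, each scaled by its own gene count so that
#' `m_GO * T_GO + m_notGO * T_notGO = m * T` exactly.
#'
#' @param W Standardized expression matrix.
#' @param members Member gene ids of the term.
#' @return List with `T_go`, `T_not`, `m_go`, `m_not`.
#' @export
partition_trm <- function(W, members) {
  blocks <- partition_genes(W, members)
  if (ncol(blocks$out_set) == 0L)
    stop("term covers the whole universe; use build_trm/fit_tblup")
  list(T_go = build_trm(blocks$in_set), T_not = build_trm(blocks$out_set),
       m_go = ncol(blocks$in_set), m_not = ncol(blocks$out_set))
}
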