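# Independent oracles used to validate the samplers and solvers. These are
# deliberately brute-force / closed-form and share no code with the
# implementation paths they check.

# Exact posterior for spike-and-slab regression with fixed hyperparameters,
# by enumeration of all 2^m models via Gaussian marginal likelihoods.
# Returns PIPs, posterior mean effects and (optionally) test predictions.
enum_spike_slab <- function(X, y, pi, sigma_b2, sigma_e2, X_test = NULL) {
  n <- nrow(X); m <- ncol(X)
  stopifnot(m <= 15)
  models <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  logw <- numeric(nrow(models))
  betas <- matrix(0, nrow(models), m)
  for (i in seq_len(nrow(models))) {
    g <- unlist(models[i, ])
    k <- sum(g)
    Sigma <- diag(sigma_e2, n)
    if (k > 0) {
      Xg <- X[, g, drop = FALSE]
      Sigma <- Sigma + sigma_b2 * tcrossprod(Xg)
    }
    ch <- chol(Sigma)
    logdet <- 2 * sum(log(diag(ch)))
    quad <- sum(backsolve(ch, y, transpose = TRUE)^2)
    logw[i] <- k * log(pi) + (m - k) * log(1 - pi) -
      0.5 * (n * log(2 * base::pi) + logdet + quad)
    if (k > 0) {
      A <- crossprod(Xg) + diag(sigma_e2 / sigma_b2, k)
      betas[i, g] <- solve(A, crossprod(Xg, y))
    }
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  pip <- colSums(w * as.matrix(models))
  beta_mean <- colSums(w * betas)
  pred <- if (!is.null(X_test)) drop(as.matrix(X_test) %*% beta_mean)
  list(pip = pip, beta_mean = beta_mean, pred = pred, weights = w)
}

# Closed-form BLUP with known variance components: posterior mean of the
# training random effect and test-line conditional expectations.
blup_closed_form <- function(T_full, train, test, y, sigma_t2, sigma_e2) {
  T11 <- T_full[train, train, drop = FALSE]
  V <- sigma_t2 * T11 + diag(sigma_e2, length(train))
  alpha <- solve(V, y)
  list(t_train = drop(sigma_t2 * T11 %*% alpha),
       pred = drop(sigma_t2 * T_full[test, train, drop = FALSE] %*% alpha))
}

# Ridge solution with penalty lambda applied in the normal equations.
ridge_oracle <- function(X, y, lambda) {
  drop(solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, y)))
}

# OLS predictions (minimum-norm when rank deficient, via the pseudoinverse).
ols_pred <- function(X, y, X_new = X) {
  sv <- svd(X)
  pos <- sv$d > sv$d[1] * 1e-10
  beta <- sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], y) / sv$d[pos])
  drop(as.matrix(X_new) %*% beta)
}

# Classical m-space PLS1 (NIPALS with deflation of X), the direct route the
# wide-kernel algorithm must agree with on small instances.
nipals_pls1 <- function(X, y, k) {
  Xd <- X; yd <- y
  W <- NULL; P <- NULL; Tm <- NULL; qv <- numeric(0)
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xd %*% w)
    t <- t / sqrt(sum(t^2))
    p <- drop(crossprod(Xd, t))
    q <- drop(crossprod(yd, t))
    W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, t)
    qv <- c(qv, q)
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - t * q
  }
  beta <- drop(W %*% solve(crossprod(P, W), qv))
  list(beta = beta, T = Tm)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
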