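# Shared CV fold assignment: shuffle indices once under the given seed, then
# deal into k contiguous blocks. Returns a list of index vectors.
make_cv_folds <- function(n, k, seed) {
  set.seed(seed)
  idx <- sample.int(n)
  split(idx, cut(seq_len(n), breaks = k, labels = FALSE))
}

#' Principal component regression with CV-selected component count
#'
#' Regresses a centered trait on the leading principal components of the
#' centered expression matrix. The number of components `k` is chosen by
#' 5-fold cross-validation inside the training set, minimizing mean squared
#' prediction error; ties go to the smaller `k`. `k = 0` (intercept-only) is
#' an admissible winner and is flagged as a degenerate model.
#'
#' @param X Centered numeric matrix (lines x genes).
#' @param y Centered numeric response.
#' @param max_k Maximum components considered; default
#'   `min(n - 1, m, 100)`, clipped with a warning if larger.
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed controlling fold assignment only.
#' @return Object of class `pcr_fit`: `k_selected`, `coefficients`
#'   (gene-space m-vector), `cv_curve` (MSE for k = 0..max_k), `failed`,
#'   `failure_cause`.
#' @export
fit_pcr <- function(X, y, max_k = NULL, cv_folds = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  stopifnot(length(y) == n)
  kmax_allowed <- min(n - 1L, m)
  if (is.null(max_k)) max_k <- min(kmax_allowed, 100L)
  if (max_k > kmax_allowed) {
    warning("max_k clipped to min(n-1, m)")
    max_k <- kmax_allowed
  }
  folds <- make_cv_folds(n, cv_folds, seed)
  sse <- matrix(0, cv_folds, max_k + 1L)
  for (fi in seq_along(folds)) {
    te <- folds[[fi]]
    Xtr <- center_columns(X[-te, , drop = FALSE])
    mu_x <- attr(Xtr, "col_means")
    ytr <- y[-te]; mu_y <- mean(ytr); ytr <- ytr - mu_y
    Xte <- sweep(X[te, , drop = FALSE], 2L, mu_x, "-")
    sv <- svd(Xtr)
    r <- sum(sv$d > sv$d[1] * 1e-10)
    kk <- min(max_k, r)
    gam <- crossprod(sv$u[, seq_len(kk), drop = FALSE], ytr) /
      sv$d[seq_len(kk)]
    sc_te <- Xte %*% sv$v[, seq_len(kk), drop = FALSE]
    pred <- rep(mu_y, length(te))
    sse[fi, 1L] <- sum((y[te] - pred)^2)
    for (k in seq_len(max_k)) {
      if (k <= kk) pred <- pred + sc_te[, k] * gam[k]
      sse[fi, k + 1L] <- sum((y[te] - pred)^2)
    }
  }
  cv_curve <- colSums(sse) / n
  k_sel <- which.min(cv_curve) - 1L
  sv <- svd(X)
  r <- sum(sv$d > sv$d[1] * 1e-10)
  k_sel <- min(k_sel, r)
  beta <- numeric(m)
  if (k_sel > 0L) {
    gam <- crossprod(sv$u[, seq_len(k_sel), drop = FALSE], y) /
      sv$d[seq_len(k_sel)]
    beta <- drop(sv$v[, seq_len(k_sel), drop = FALSE] %*% gam)
  }
  structure(list(k_selected = k_sel, coefficients = beta,
                 cv_curve = stats::setNames(cv_curve, 0:max_k),
                 converged = TRUE,
                 failed = k_sel == 0L,
                 failure_cause = if (k_sel == 0L) "intercept-only" else NA_character_),
            class = "pcr_fit")
}

#' @export
predict.pcr_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients)
}

# Wide-kernel PLS components for a single response. Works on the n x n
# cross-product matrix K = XX' (suited to m >> n); gene-space weights and
# loadings are recovered as X'u and X't, which is valid because successive
# score vectors are mutually orthogonal.
plsr_components <- function(X, y, k, max_iter = 100L, tol = 1e-10) {
  n <- nrow(X)
  K <- tcrossprod(X)
  Tm <- matrix(0, n, 0); Wm <- matrix(0, ncol(X), 0)
  Pm <- matrix(0, ncol(X), 0); qv <- numeric(0)
  y_cur <- y
  converged <- TRUE
  for (a in seq_len(k)) {
    if (sqrt(sum(y_cur^2)) < 1e-12) break
    u <- y_cur
    t_old <- NULL
    ok <- FALSE
    dead <- FALSE
    for (it in seq_len(max_iter)) {
      t <- drop(K %*% u)
      nt <- sqrt(sum(t^2))
      if (nt < 1e-10) { dead <- TRUE; break }
      t <- t / nt
      if (!is.null(t_old) && sqrt(sum((t - t_old)^2)) < tol) { ok <- TRUE; break }
      t_old <- t
      u <- y_cur * drop(crossprod(y_cur, t))  # univariate y-score update
    }
    if (dead) break
    if (!ok) converged <- FALSE
    q <- drop(crossprod(y_cur, t))
    Tm <- cbind(Tm, t); qv <- c(qv, q)
    Wm <- cbind(Wm, drop(crossprod(X, y_cur)))  # univariate y-score is y_cur
    Pm <- cbind(Pm, drop(crossprod(X, t)))
    y_cur <- y_cur - t * q
    Kt <- K %*% t
    K <- K - tcrossprod(t, Kt) - tcrossprod(Kt, t) +
      tcrossprod(t) * drop(crossprod(t, Kt))
  }
  list(T = Tm, W = Wm, P = Pm, q = qv, converged = converged)
}

# Gene-space regression vector from the first k PLS components.
plsr_beta <- function(comp, k) {
  if (k == 0L) return(numeric(nrow(comp$W)))
  W <- comp$W[, seq_len(k), drop = FALSE]
  P <- comp$P[, seq_len(k), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), comp$q[seq_len(k)]))
}

#' Partial least squares regression (wide-kernel algorithm)
#'
#' PLS for a single trait computed through the `n x n` cross-product matrix,
#' the route suited to wide (`m >> n`) expression matrices. Components
#' maximize covariance with the response; the number of components is chosen
#' by 5-fold CV as in [fit_pcr()]. If the iterative score extraction fails
#' to settle within `max_iter` iterations the fit is returned with
#' `converged = FALSE` and flagged as a failure (a recorded model failure,
#' not an exception). `max_iter` defaults to 100 and can be raised (e.g. to
#' 500) for hard instances.
#'
#' @inheritParams fit_pcr
#' @param max_iter Maximum iterations of the per-component score loop.
#' @param tol Convergence tolerance on successive score vectors.
#' @return Object of class `plsr_fit` with the same fields as `pcr_fit`
#'   plus `converged`.
#' @export
fit_plsr <- function(X, y, max_k = NULL, cv_folds = 5L, max_iter = 100L,
                     tol = 1e-10, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  stopifnot(length(y) == n)
  kmax_allowed <- min(n - 1L, m)
  if (is.null(max_k)) max_k <- min(kmax_allowed, 100L)
  if (max_k > kmax_allowed) {
    warning("max_k clipped to min(n-1, m)")
    max_k <- kmax_allowed
  }
  folds <- make_cv_folds(n, cv_folds, seed)
  sse <- matrix(0, cv_folds, max_k + 1L)
  all_conv <- TRUE
  for (fi in seq_along(folds)) {
    te <- folds[[fi]]
    Xtr <- center_columns(X[-te, , drop = FALSE])
    mu_x <- attr(Xtr, "col_means")
    ytr <- y[-te]; mu_y <- mean(ytr); ytr <- ytr - mu_y
    Xte <- sweep(X[te, , drop = FALSE], 2L, mu_x, "-")
    comp <- plsr_components(Xtr, ytr, max_k, max_iter, tol)
    if (!comp$converged) all_conv <- FALSE
    kk <- length(comp$q)
    sse[fi, 1L] <- sum((y[te] - mu_y)^2)
    for (k in seq_len(max_k)) {
      beta_k <- plsr_beta(comp, min(k, kk))
      pred <- mu_y + drop(Xte %*% beta_k)
      sse[fi, k + 1L] <- sum((y[te] - pred)^2)
    }
  }
  cv_curve <- colSums(sse) / n
  k_sel <- which.min(cv_curve) - 1L
  beta <- numeric(m)
  if (k_sel > 0L) {
    comp <- plsr_components(X, y, k_sel, max_iter, tol)
    if (!comp$converged) all_conv <- FALSE
    k_sel <- min(k_sel, length(comp$q))
    beta <- plsr_beta(comp, k_sel)
  }
  failed <- !all_conv || k_sel == 0L
  structure(list(k_selected = k_sel, coefficients = beta,
                 cv_curve = stats::setNames(cv_curve, 0:max_k),
                 converged = all_conv, failed = failed,
                 failure_cause = if (!all_conv) "non-convergence"
                 else if (k_sel == 0L) "intercept-only" else NA_character_),
            class = "plsr_fit")
}

#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients)
}
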