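# Common glmnet path + 5-fold CV wrapper for ridge (alpha = 0) and LASSO
# (alpha = 1). Fold assignment follows the package-wide rule: shuffle
# indices once under the seed, deal into contiguous blocks.
fit_glmnet_cv <- function(X, y, alpha, n_lambda, lambda_min_ratio, cv_folds,
                          seed, rule, standardize, lambda, thresh) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- make_cv_folds(n, cv_folds, seed)
  foldid <- integer(n)
  for (i in seq_along(folds)) foldid[folds[[i]]] <- i
  args <- list(x = X, y = y, alpha = alpha, foldid = foldid,
               standardize = standardize, thresh = thresh)
  if (is.null(lambda)) {
    args$nlambda <- n_lambda
    args$lambda.min.ratio <- lambda_min_ratio
  } else args$lambda <- lambda
  cvfit <- do.call(glmnet::cv.glmnet, args)
  lam <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
  beta <- drop(as.matrix(coef(cvfit, s = lam)))
  intercept <- beta[1L]
  beta <- beta[-1L]
  nnz <- sum(beta != 0)
  structure(list(lambda_grid = cvfit$lambda, lambda_selected = lam,
                 coefficients = beta, intercept = intercept,
                 n_nonzero = nnz, intercept_only = nnz == 0L,
                 cv_curve = cvfit$cvm, cvfit = cvfit,
                 failed = (alpha == 1 && nnz == 0L),
                 failure_cause = if (alpha == 1 && nnz == 0L)
                   "intercept-only" else NA_character_),
            class = "penalized_fit")
}

#' Ridge regression over a penalty path with CV-selected lambda
#'
#' L2-penalized least squares via the glmnet coordinate-descent path solver,
#' with the penalty chosen by 5-fold cross-validation (CV-error minimizer by
#' default; the one-SE rule behind `rule = "1se"`). Columns are standardized
#' inside the solver and coefficients are returned on the original scale
#' (the solver's default, which defines the scale of lambda).
#'
#' @param X Centered numeric matrix (lines x genes).
#' @param y Centered numeric response.
#' @param n_lambda Grid size (default 100 log-spaced values).
#' @param lambda_min_ratio Smallest/largest penalty ratio (default 1e-4).
#' @param cv_folds CV folds (default 5).
#' @param seed Seed controlling fold assignment only; the fit itself is
#'   deterministic.
#' @param rule `"min"` (CV minimizer, default) or `"1se"`.
#' @param standardize Standardize predictors inside the solver (default
#'   TRUE).
#' @param lambda Optional explicit descending penalty grid.
#' @param thresh Coordinate-descent convergence threshold.
#' @return Object of class `penalized_fit`: `lambda_grid`,
#'   `lambda_selected`, `coefficients` (m-vector), `intercept`,
#'   `n_nonzero`, `intercept_only`, `cv_curve`, failure flags.
#' @export
fit_ridge <- function(X, y, n_lambda = 100L, lambda_min_ratio = 1e-4,
                      cv_folds = 5L, seed = 1L, rule = c("min", "1se"),
                      standardize = TRUE, lambda = NULL, thresh = 1e-7) {
  rule <- match.arg(rule)
  fit_glmnet_cv(X, y, alpha = 0, n_lambda, lambda_min_ratio, cv_folds,
                seed, rule, standardize, lambda, thresh)
}

#' LASSO regression over a penalty path with CV-selected lambda
#'
#' L1-penalized least squares via the glmnet coordinate-descent path solver;
#' performs variable selection by zeroing coefficients. The path starts at
#' the smallest penalty giving an all-zero solution (`lambda_max =
#' max_j |x_j' y| / n` for unstandardized columns) and descends four decades.
#' A CV-selected solution with no active coefficients is an intercept-only
#' model: a recorded failure (`intercept_only = TRUE`), not an error.
#'
#' @inheritParams fit_ridge
#' @return Object of class `penalized_fit` (see [fit_ridge()]).
#' @export
fit_lasso <- function(X, y, n_lambda = 100L, lambda_min_ratio = 1e-4,
                      cv_folds = 5L, seed = 1L, rule = c("min", "1se"),
                      standardize = TRUE, lambda = NULL, thresh = 1e-7) {
  rule <- match.arg(rule)
  fit_glmnet_cv(X, y, alpha = 1, n_lambda, lambda_min_ratio, cv_folds,
                seed, rule, standardize, lambda, thresh)
}

#' @export
predict.penalized_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

#' Smallest penalty with an all-zero LASSO solution
#'
#' For centered, unstandardized columns and the 1/(2n) loss scaling,
#' `lambda_max = max_j |x_j' y| / n`.
#'
#' @param X Centered numeric matrix.
#' @param y Centered numeric response.
#' @return The closed-form entry penalty.
#' @export
lasso_lambda_max <- function(X, y) {
  max(abs(crossprod(as.matrix(X), as.numeric(y)))) / nrow(X)
}
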