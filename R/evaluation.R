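#' Replicated train/test split plan
#'
#' Builds the evaluation protocol's split plan: `n_reps` (default 25)
#' random partitions with a held-out test fraction of 10%. The test size is
#' `round(test_fraction * n)` (e.g. 20 of 198 lines). Replicate `k` draws
#' its split under seed `base_seed + k`, so the whole plan is reproducible
#' and can be shared across every method being compared.
#'
#' @param n Number of lines (at least 20).
#' @param n_reps Number of replicates (default 25).
#' @param test_fraction Held-out fraction (default 0.1).
#' @param base_seed Integer base seed.
#' @return Object of class `split_plan`: list of
#'   `list(train, test, seed)` with attributes `n`, `base_seed`.
#' @export
make_splits <- function(n, n_reps = 25L, test_fraction = 0.1,
                        base_seed = 1L) {
  if (n < 20L) stop("need at least 20 lines")
  n_test <- round(test_fraction * n)
  if (n_test == 0L) stop("test fraction rounds to zero lines")
  reps <- lapply(seq_len(n_reps), function(k) {
    set.seed(base_seed + k)
    test <- sort(sample.int(n, n_test))
    list(train = setdiff(seq_len(n), test), test = test,
         seed = base_seed + k)
  })
  structure(reps, n = n, n_reps = n_reps, test_fraction = test_fraction,
            base_seed = base_seed, class = "split_plan")
}

#' Prediction accuracy as observed/predicted correlation
#'
#' Pearson correlation between observed and predicted phenotypes in a test
#' set. If either vector has zero variance (e.g. an intercept-only model
#' predicting a constant) the correlation is undefined: the function
#' returns `NA` with the failure cause recorded in the
#' `"failure_cause"` attribute rather than erroring.
#'
#' @param y_obs,y_pred Equal-length numeric vectors (length at least 3).
#' @return Correlation, or `NA` with attribute `failure_cause`.
#' @export
accuracy <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop("length mismatch")
  if (length(y_obs) < 3L) stop("need at least 3 test lines")
  if (anyNA(y_pred) || any(!is.finite(y_pred)))
    return(structure(NA_real_, failure_cause = "non-finite prediction"))
  if (stats::sd(y_pred) == 0)
    return(structure(NA_real_, failure_cause = "zero-variance prediction"))
  if (stats::sd(y_obs) == 0)
    return(structure(NA_real_, failure_cause = "zero-variance observation"))
  cor(y_obs, y_pred)
}

#' Aggregate per-replicate accuracies into a method summary
#'
#' Computes, per method (and per stratum when a `stratum` column is
#' present), the mean and standard error of the replicate correlations over
#' successful replicates only, the failure count and percentage, and the
#' exclusion flag: a method is excluded when it failed in more than 40% of
#' replicates in at least one stratum (the protocol's reliability rule).
#'
#' @param results Data frame with columns `method`, `replicate`, `r`
#'   (NA = failure), optionally `failure_cause` and `stratum`.
#' @return Data frame of class `accuracy_table`: one row per method (x
#'   stratum), columns `mean_r`, `se_r`, `n_success`, `n_failed`,
#'   `pct_failed`, `excluded`.
#' @export
aggregate_accuracy <- function(results) {
  stopifnot(all(c("method", "replicate", "r") %in% names(results)))
  if (!nrow(results)) stop("no replicates supplied")
  has_strata <- "stratum" %in% names(results)
  key <- if (has_strata) interaction(results$method, results$stratum,
                                     drop = TRUE, sep = "\r")
         else factor(results$method)
  rows <- lapply(levels(key), function(kv) {
    sub <- results[key == kv, , drop = FALSE]
    ok <- !is.na(sub$r)
    n_rep <- nrow(sub)
    n_succ <- sum(ok)
    data.frame(method = sub$method[1],
               stratum = if (has_strata) sub$stratum[1] else NA_character_,
               mean_r = if (n_succ) mean(sub$r[ok]) else NA_real_,
               se_r = if (n_succ > 1L) stats::sd(sub$r[ok]) / sqrt(n_succ)
                      else if (n_succ == 1L) 0 else NA_real_,
               n_success = n_succ, n_failed = n_rep - n_succ,
               pct_failed = 100 * (n_rep - n_succ) / n_rep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # exclusion applies method-wide: > 40% failures in at least one stratum
  bad <- tapply(out$pct_failed > 40 | out$n_success == 0L, out$method, any)
  out$excluded <- as.logical(bad[out$method])
  if (!has_strata) out$stratum <- NULL
  class(out) <- c("accuracy_table", "data.frame")
  out
}

#' Built-in prediction method wrappers for the evaluation harness
#'
#' Returns the standard method set as harness functions. Each wrapper takes
#' the raw expression matrix, the full phenotype vector, train/test index
#' vectors and a seed; centers the training data; fits; and returns
#' test-set predictions on the original trait scale (training mean added
#' back). Kernel methods standardize the full expression matrix once and
#' condition on the training block. Degenerate fits (intercept-only,
#' non-convergence) are returned as recorded failures. Additional
#' predictors (e.g. random forests) can be plugged in by supplying any
#' function with the same signature.
#'
#' @param mcmc_scale Multiplier in (0, 1] applied to the default MCMC
#'   schedules; use values < 1 for quick comparisons.
#' @return Named list of functions
#'   `function(X, y, train, test, seed) -> list(pred, failed, cause)`.
#' @export
builtin_methods <- function(mcmc_scale = 1) {
  sc <- function(x) max(20L, as.integer(round(x * mcmc_scale)))
  # keep (n_iter - burn_in) an exact multiple of thin, about 2000 retained
  fix_sched <- function(total, burn) {
    thin <- max(1L, as.integer(floor((total - burn) / 2000)))
    len <- ((total - burn) %/% thin) * thin
    list(n_iter = burn + len, burn_in = burn, thin = thin)
  }
  sched_bc <- fix_sched(sc(130000), sc(30000))
  sched_tb <- fix_sched(sc(85000), sc(10000))

  regression_wrapper <- function(fitter) {
    function(X, y, train, test, seed) {
      Xtr <- center_columns(X[train, , drop = FALSE])
      mu_x <- attr(Xtr, "col_means")
      mu_y <- mean(y[train])
      Xte <- sweep(X[test, , drop = FALSE], 2L, mu_x, "-")
      fit <- fitter(Xtr, y[train] - mu_y, seed)
      list(pred = predict(fit, Xte) + mu_y,
           failed = isTRUE(fit$failed),
           cause = fit$failure_cause)
    }
  }
  list(
    pcr = regression_wrapper(function(X, y, seed)
      fit_pcr(X, y, seed = seed)),
    plsr = regression_wrapper(function(X, y, seed)
      fit_plsr(X, y, seed = seed)),
    ridge = regression_wrapper(function(X, y, seed)
      fit_ridge(X, y, seed = seed)),
    lasso = regression_wrapper(function(X, y, seed)
      fit_lasso(X, y, seed = seed)),
    bayesc = regression_wrapper(function(X, y, seed)
      fit_bayesc(X, y, n_iter = sched_bc$n_iter,
                 burn_in = sched_bc$burn_in, thin = sched_bc$thin,
                 seed = seed, warn = FALSE)),
    varbvs = regression_wrapper(function(X, y, seed)
      fit_varbvs(X, y)),
    mrash = regression_wrapper(function(X, y, seed) {
      las <- fit_lasso(X, y, seed = seed)
      fit_mrash(X, y, beta_init = las$coefficients)
    }),
    tblup = function(X, y, train, test, seed) {
      W <- suppressWarnings(standardize_expression(X))
      T <- build_trm(W)
      mu_y <- mean(y[train])
      fit <- fit_tblup(T, y[train] - mu_y, train = train, test = test,
                       n_iter = sched_tb$n_iter,
                       burn_in = sched_tb$burn_in,
                       thin = sched_tb$thin, seed = seed, warn = FALSE)
      list(pred = fit$predictions + mu_y, failed = isTRUE(fit$failed),
           cause = fit$failure_cause)
    }
  )
}

#' Run the replicated train/test evaluation for a set of methods
#'
#' Applies every method to the identical split plan (the protocol requires
#' shared splits for comparability) and records the per-replicate test-set
#' correlation or the failure cause. Per replicate, each method receives a
#' seed derived deterministically from the replicate seed and the method
#' name, so chains differ across methods while splits are shared.
#'
#' @param X Raw lines-by-genes expression matrix.
#' @param y Phenotype vector aligned to the rows of `X`.
#' @param methods Named list of harness functions (see
#'   [builtin_methods()]).
#' @param plan A [make_splits()] plan over `nrow(X)` lines.
#' @param verbose Print a progress line per method.
#' @return Data frame with columns `method`, `replicate`, `r`,
#'   `failure_cause`, carrying the plan as attribute `plan`.
#' @export
evaluate_methods <- function(X, y, methods, plan, verbose = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), attr(plan, "n") == nrow(X))
  out <- vector("list", length(methods) * length(plan))
  i <- 0L
  for (mname in names(methods)) {
    if (verbose) message("evaluating ", mname)
    fn <- methods[[mname]]
    for (k in seq_along(plan)) {
      sp <- plan[[k]]
      seed <- derive_seed(sp$seed, mname)
      res <- tryCatch(fn(X, y, sp$train, sp$test, seed),
                      error = function(e)
                        list(pred = rep(NA_real_, length(sp$test)),
                             failed = TRUE, cause = "runtime error"))
      if (isTRUE(res$failed)) {
        r <- NA_real_
        cause <- if (is.null(res$cause) || is.na(res$cause))
          "model failure" else res$cause
      } else {
        r <- accuracy(y[sp$test], res$pred)
        cause <- attr(r, "failure_cause")
        if (is.null(cause)) cause <- NA_character_
        r <- as.numeric(r)
      }
      i <- i + 1L
      out[[i]] <- data.frame(method = mname, replicate = k, r = r,
                             failure_cause = cause,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "plan") <- plan
  res
}
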