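# Shared small kernel fixture: standardized expression and full TRM.
tblup_fixture <- function(n = 60, m = 80, h2 = 0.8, seed = 41) {
  cfg <- sim_config(n_lines = n, n_genes = m, architecture = "dense",
                    target_H2m = h2, seed = seed)
  ds <- simulate_trait(simulate_expression(cfg), cfg)
  W <- standardize_expression(ds$expression)
  list(W = W, T = build_trm(W), y = ds$phenotype, ds = ds)
}

test_that("fixed-variance TBLUP matches the closed-form BLUP", {
  fx <- tblup_fixture()
  n <- nrow(fx$T)
  train <- 1:50; test <- 51:60
  y <- fx$y[train] - mean(fx$y[train])
  st2 <- 0.8 * var(y); se2 <- 0.2 * var(y)
  fit <- fit_tblup(fx$T, y, train = train, test = test,
                   n_iter = 6000, burn_in = 1000, thin = 1,
                   fixed = list(sigma_t2 = st2, sigma_e2 = se2),
                   seed = 3, warn = FALSE)
  oracle <- blup_closed_form(fx$T, train, test, y, st2, se2)
  mc_se <- sd(fit$t_train - oracle$t_train) + 0.02 * sd(y)
  expect_lt(max(abs(fit$t_train - oracle$t_train)), 3 * mc_se)
  expect_lt(max(abs(fit$predictions - oracle$pred)), 3 * mc_se)
  expect_gt(cor(fit$predictions, oracle$pred), 0.999)
})

test_that("TBLUP with fixed variance ratio equals ridge on W", {
  fx <- tblup_fixture(n = 50, m = 120, seed = 42)
  train <- 1:40; test <- 41:50
  y <- fx$y[train] - mean(fx$y[train])
  st2 <- var(y) * 0.6; se2 <- var(y) * 0.4
  m <- ncol(fx$W)
  lambda <- m * se2 / st2
  beta_ridge <- ridge_oracle(fx$W[train, ], y, lambda)
  pred_ridge <- drop(fx$W[test, ] %*% beta_ridge)
  fit <- fit_tblup(fx$T, y, train = train, test = test,
                   n_iter = 6000, burn_in = 1000, thin = 1,
                   fixed = list(sigma_t2 = st2, sigma_e2 = se2),
                   seed = 4, warn = FALSE)
  expect_gt(cor(fit$predictions, pred_ridge), 0.999)
  expect_lt(max(abs(fit$predictions - pred_ridge)),
            3 * (sd(fit$predictions - pred_ridge) + 0.02 * sd(y)))
})

test_that("a zero transcriptomic variance predicts the training mean", {
  fx <- tblup_fixture(n = 40, m = 30, seed = 43)
  train <- 1:30; test <- 31:40
  y <- fx$y[train] - mean(fx$y[train])
  fit <- fit_tblup(fx$T, y, train = train, test = test,
                   n_iter = 500, burn_in = 100, thin = 1,
                   fixed = list(sigma_t2 = 0), seed = 5, warn = FALSE)
  expect_true(all(fit$predictions == 0))  # centered scale: the mean
})

test_that("matched two-kernel variances reproduce the single-kernel model", {
  fx <- tblup_fixture(n = 50, m = 60, seed = 44)
  members <- colnames(fx$W)[1:20]
  part <- partition_trm(fx$W, members)
  train <- 1:40; test <- 41:50
  y <- fx$y[train] - mean(fx$y[train])
  # sigma proportional to block sizes: the summed kernel model equals the
  # full TRM model because m_GO T_GO + m_notGO T_notGO = m T
  st2 <- 0.7 * var(y); se2 <- 0.3 * var(y)
  m <- ncol(fx$W)
  fit2 <- fit_go_tblup(part$T_go, part$T_not, y, train = train,
                       test = test,
                       n_iter = 6000, burn_in = 1000, thin = 1,
                       fixed = list(sigma_go2 = st2 * part$m_go / m,
                                    sigma_not2 = st2 * part$m_not / m,
                                    sigma_e2 = se2),
                       seed = 6, warn = FALSE)
  oracle <- blup_closed_form(fx$T, train, test, y, st2, se2)
  expect_gt(cor(fit2$predictions, oracle$pred), 0.995)
  expect_lt(max(abs(fit2$predictions - oracle$pred)),
            4 * (sd(fit2$predictions - oracle$pred) + 0.02 * sd(y)))
})

test_that("empty gene blocks are rejected", {
  fx <- tblup_fixture(n = 30, m = 20, seed = 45)
  expect_error(partition_trm(fx$W, colnames(fx$W)), "whole universe")
  T_bad <- fx$T
  attr(T_bad, "scale_m") <- 0L
  expect_error(fit_go_tblup(T_bad, fx$T, fx$y - mean(fx$y)),
               "nonempty")
})

test_that("GO-TBLUP attributes the variance to an enriched causal term", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_lines = 70, n_genes = 80,
                      architecture = "go_enriched", n_causal = 10,
                      target_H2m = 0.8, n_factors = 0, seed = 700 + s)
    ds <- simulate_dataset(cfg, n_terms = 4, size_range = c(10, 14))
    W <- standardize_expression(ds$expression)
    members <- intersect(ds$genesets[[ds$config$causal_term]], colnames(W))
    part <- partition_trm(W, members)
    y <- ds$phenotype - mean(ds$phenotype)
    fit <- fit_go_tblup(part$T_go, part$T_not, y,
                        n_iter = 1500, burn_in = 300, thin = 2,
                        seed = s, warn = FALSE)
    if (fit$go_share >= 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("prediction accuracy rises with heritability", {
  mean_r <- vapply(c(0.2, 0.5, 0.8), function(h2) {
    rs <- vapply(1:5, function(s) {
      cfg <- sim_config(n_lines = 60, n_genes = 100,
                        architecture = "dense", target_H2m = h2,
                        seed = 900 + s + round(1000 * h2))
      ds <- simulate_trait(simulate_expression(cfg), cfg)
      W <- standardize_expression(ds$expression)
      T <- build_trm(W)
      train <- 1:48; test <- 49:60
      y <- ds$phenotype[train] - mean(ds$phenotype[train])
      fit <- fit_tblup(T, y, train = train, test = test,
                       n_iter = 1200, burn_in = 200, thin = 2,
                       seed = s, warn = FALSE)
      cor(ds$phenotype[test], fit$predictions)
    }, 0)
    mean(rs)
  }, 0)
  expect_true(mean_r[3] > mean_r[1])
  expect_gt(cor(mean_r, c(0.2, 0.5, 0.8), method = "spearman"), 0)
})
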