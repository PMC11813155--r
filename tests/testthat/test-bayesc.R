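test_that("schedule arithmetic and validation", {
  # the default schedule retains (130000 - 30000) / 50 = 2000 draws
  expect_equal((130000 - 30000) / 50, 2000)
  d <- toy_xy(n = 20, m = 3, seed = 31)
  fit <- fit_bayesc(d$X, d$y, n_iter = 600, burn_in = 100, thin = 5,
                    seed = 1, warn = FALSE)
  expect_equal(fit$retained_draws, 100L)
  expect_equal(nrow(fit$variance_draws), 100L)
  expect_error(fit_bayesc(d$X, d$y, n_iter = 100, burn_in = 200),
               "burn_in")
  expect_error(fit_bayesc(d$X, d$y, n_iter = 1000, burn_in = 100,
                          thin = 7), "multiple")
})

test_that("Gibbs PIPs match exhaustive model enumeration", {
  d <- toy_xy(n = 40, m = 5, beta = c(1, -1, 0, 0, 0), sd = 0.7, seed = 32)
  hp <- list(pi = 0.3, sigma_b2 = 0.5, sigma_e2 = 0.49)
  oracle <- enum_spike_slab(d$X, d$y, hp$pi, hp$sigma_b2, hp$sigma_e2)
  fit <- fit_bayesc(d$X, d$y, n_iter = 22000, burn_in = 2000, thin = 10,
                    fixed = hp, seed = 5, warn = FALSE)
  expect_lt(max(abs(fit$pip - oracle$pip)), 0.05)
  expect_lt(max(abs(fit$effect_means - oracle$beta_mean)), 0.05 * sd(d$y))
})

test_that("null data: sampler PIPs agree with the oracle under fixed pi", {
  set.seed(33)
  X <- scale(matrix(rnorm(40 * 5), 40, 5), scale = FALSE)
  y <- rnorm(40); y <- y - mean(y)
  hp <- list(pi = 0.1, sigma_b2 = 0.5, sigma_e2 = var(y))
  oracle <- enum_spike_slab(X, y, hp$pi, hp$sigma_b2, hp$sigma_e2)
  fit <- fit_bayesc(X, y, n_iter = 22000, burn_in = 2000, thin = 10,
                    fixed = hp, seed = 6, warn = FALSE)
  # mean PIP within 3 binomial-style Monte-Carlo SEs of the oracle mean
  mc_se <- sqrt(mean(oracle$pip * (1 - oracle$pip)) / fit$retained_draws) +
    0.01
  expect_lt(abs(mean(fit$pip) - mean(oracle$pip)), 3 * mc_se + 0.02)
  expect_lt(max(fit$pip), 0.5)
})

test_that("permuting gene columns permutes PIPs (oracle protocol)", {
  d <- toy_xy(n = 35, m = 5, beta = c(1.5, 0, -1, 0, 0), seed = 34)
  hp <- list(pi = 0.25, sigma_b2 = 0.4, sigma_e2 = 0.3)
  perm <- c(4, 2, 5, 1, 3)
  o1 <- enum_spike_slab(d$X, d$y, hp$pi, hp$sigma_b2, hp$sigma_e2)
  f1 <- fit_bayesc(d$X, d$y, n_iter = 12000, burn_in = 2000, thin = 5,
                   fixed = hp, seed = 7, warn = FALSE)
  f2 <- fit_bayesc(d$X[, perm], d$y, n_iter = 12000, burn_in = 2000,
                   thin = 5, fixed = hp, seed = 8, warn = FALSE)
  expect_lt(max(abs(o1$pip[perm] - unname(f2$pip))), 0.06)
  expect_lt(max(abs(unname(f1$pip)[perm] - unname(f2$pip))), 0.1)
})

test_that("prior calibration follows the variance-explained arithmetic", {
  set.seed(35)
  y <- rnorm(100, sd = 2)
  cal <- calibrate_priors(y, list(list(type = "kernel", mean_diag = 1)),
                          R2 = 0.8)
  expect_equal(cal$residual$mode, 0.2 * var(y))
  expect_equal(cal$components[[1]]$mode, 0.8 * var(y))
  # two equal components split the variance-explained budget
  cal2 <- calibrate_priors(y, list(list(type = "kernel", mean_diag = 1),
                                   list(type = "kernel", mean_diag = 1)),
                           R2 = 0.8)
  expect_equal(cal2$components[[1]]$prior_ve, 0.4 * var(y))
  expect_equal(cal2$components[[2]]$prior_ve, 0.4 * var(y))
  # doubling Var(y) doubles every scale
  y2 <- y * sqrt(2)
  cal4 <- calibrate_priors(y2, list(list(type = "effects", msx = 3,
                                         pi = 0.5)), R2 = 0.8)
  cal5 <- calibrate_priors(y, list(list(type = "effects", msx = 3,
                                        pi = 0.5)), R2 = 0.8)
  expect_equal(cal4$residual$S / cal5$residual$S, 2, tolerance = 1e-10)
  expect_equal(cal4$components[[1]]$S / cal5$components[[1]]$S, 2,
               tolerance = 1e-10)
  expect_error(calibrate_priors(y, list(list(type = "kernel",
                                             mean_diag = 1)), R2 = 1.2),
               "R2")
})

test_that("a whole-universe term reduces the two-group model to BayesC", {
  d <- toy_xy(n = 30, m = 6, seed = 36)
  colnames(d$X) <- paste0("g", 1:6)
  f1 <- fit_bayesc(d$X, d$y, n_iter = 3000, burn_in = 500, thin = 5,
                   seed = 9, warn = FALSE)
  f2 <- fit_go_bayesc(d$X, d$y, members = paste0("g", 1:6),
                      n_iter = 3000, burn_in = 500, thin = 5, seed = 9,
                      warn = FALSE)
  expect_identical(unname(f1$pip), unname(f2$pip))
  expect_identical(unname(f1$effect_means), unname(f2$effect_means))
  expect_error(fit_go_bayesc(d$X, d$y, members = character(0)), "nonempty")
  expect_error(fit_go_bayesc(d$X, d$y, members = "nope"), "nonempty|subset")
})

test_that("matched group hyperparameters reproduce the single-group fit", {
  d <- toy_xy(n = 40, m = 6, beta = c(1, -1, 0.5, 0, 0, 0), seed = 37)
  colnames(d$X) <- paste0("g", 1:6)
  hp <- list(pi = 0.3, sigma_b2 = 0.4, sigma_e2 = 0.5)
  oracle <- enum_spike_slab(d$X, d$y, hp$pi, hp$sigma_b2, hp$sigma_e2)
  f2 <- fit_go_bayesc(d$X, d$y, members = paste0("g", c(1, 3, 5)),
                      n_iter = 22000, burn_in = 2000, thin = 10,
                      fixed = hp, seed = 11, warn = FALSE)
  # identical fixed hyperparameters in both groups = one common prior
  expect_lt(max(abs(unname(f2$pip) - oracle$pip)), 0.05)
})

test_that("the GO group absorbs the signal in an enriched simulation", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_lines = 80, n_genes = 60,
                      architecture = "go_enriched", n_causal = 8,
                      target_H2m = 0.8, n_factors = 0, seed = 500 + s)
    ds <- simulate_dataset(cfg, n_terms = 4, size_range = c(8, 12))
    Xc <- center_columns(unclass(ds$expression))
    yc <- ds$phenotype - mean(ds$phenotype)
    members <- ds$genesets[[ds$config$causal_term]]
    fit <- fit_go_bayesc(Xc, yc, members = members, n_iter = 2500,
                         burn_in = 500, thin = 2, seed = s, warn = FALSE)
    pi_go <- fit$pi_mean[["pi_1"]]
    pi_not <- fit$pi_mean[["pi_2"]]
    if (pi_go > pi_not) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
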