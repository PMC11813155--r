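test_that("line-mean heritability formula and config validation", {
  # 1 / (1 + 1/4) = 0.8
  expect_equal(h2m_line_means(1, 1, 4), 0.8)
  expect_equal(sim_config(sigma_G2 = 1, sigma_E2 = 1, f = 4)$target_H2m, 0.8)
  expect_error(sim_config(sigma_G2 = 1, sigma_E2 = 1, f = 4,
                          target_H2m = 0.5), "inconsistent")
  expect_error(sim_config(target_H2m = 1), "target_H2m")
  expect_error(sim_config(n_lines = 0), "nonpositive|dimensions")
  expect_error(sim_config(n_genes = 50, n_causal = 60,
                          architecture = "sparse"), "n_causal")
})

test_that("expression generator: determinism, factor rank, null correlation", {
  cfg <- sim_config(n_lines = 30, n_genes = 40, n_factors = 3, seed = 5)
  X1 <- simulate_expression(cfg)
  X2 <- simulate_expression(cfg)
  expect_identical(unclass(X1), unclass(X2))
  # noiseless factor part has rank k
  cfg1 <- sim_config(n_lines = 4, n_genes = 3, n_factors = 1, seed = 2)
  set.seed(cfg1$seed)
  E <- matrix(rnorm(4 * 3), 4, 3)
  L <- matrix(rnorm(4), 4, 1); F <- matrix(rnorm(3), 3, 1)
  expect_equal(qr(tcrossprod(L, F))$rank, 1L)
  expect_equal(unclass(simulate_expression(cfg1)),
               E + tcrossprod(L, F), ignore_attr = TRUE)
  # with no factors, mean |pairwise r| matches the independent-Gaussian null
  # E|r| ~= sqrt(2 / (pi n)); check within 3 Monte-Carlo SE
  cfg0 <- sim_config(n_lines = 50, n_genes = 60, n_factors = 0, seed = 9)
  X0 <- simulate_expression(cfg0)
  cors <- abs(cor(unclass(X0))[upper.tri(diag(60))])
  null_mean <- sqrt(2 / (pi * 50))
  mc_se <- sd(cors) / sqrt(length(cors))  # correlated pairs: conservative x3
  expect_lt(abs(mean(cors) - null_mean), 3 * mc_se + 0.01)
  # factors induce visibly more correlation than the null
  Xf <- simulate_expression(sim_config(n_lines = 50, n_genes = 60,
                                       n_factors = 5, seed = 9))
  corf <- abs(cor(unclass(Xf))[upper.tri(diag(60))])
  expect_gt(mean(corf), mean(cors) * 1.5)
})

test_that("trait generator hits the target heritability and architecture", {
  cfg <- sim_config(n_lines = 150, n_genes = 200, architecture = "sparse",
                    n_causal = 10, target_H2m = 0.8, seed = 21)
  ds <- simulate_trait(simulate_expression(cfg), cfg)
  expect_equal(sum(ds$true_effects != 0), 10L)
  expect_lt(abs(ds$realized_H2m - 0.8), 0.1)
  # true genetic values are W beta on the standardized scale
  W <- standardize_expression(ds$expression)
  expect_equal(drop(W %*% ds$true_effects[colnames(W)]),
               ds$true_genetic_values, tolerance = 1e-10,
               ignore_attr = TRUE)
  # null trait: no effects, pure noise
  cfg0 <- sim_config(n_lines = 50, n_genes = 30, target_H2m = 0,
                     architecture = "dense", seed = 3)
  ds0 <- simulate_trait(simulate_expression(cfg0), cfg0)
  expect_true(all(ds0$true_effects == 0))
  expect_equal(ds0$realized_H2m, 0)
  # explicit variance components: Var(g) is scaled to sigma_G2 exactly
  cfgv <- sim_config(n_lines = 60, n_genes = 50, architecture = "dense",
                     sigma_G2 = 2, sigma_E2 = 2, f = 4, seed = 8)
  dsv <- simulate_trait(simulate_expression(cfgv), cfgv)
  expect_equal(var(dsv$true_genetic_values), 2, tolerance = 1e-10)
})

test_that("realized heritability converges to its target at large n", {
  cfg <- sim_config(n_lines = 1000, n_genes = 300, architecture = "dense",
                    target_H2m = 0.8, seed = 31)
  ds <- simulate_trait(simulate_expression(cfg), cfg)
  expect_lt(abs(ds$realized_H2m - 0.8), 0.02)
})

test_that("gene-set generator: sizes, causal containment, determinism", {
  genes <- sprintf("gene_%04d", 1:100)
  gs1 <- simulate_genesets(genes, n_terms = 10, size_range = c(5, 20),
                           seed = 4)
  expect_length(gs1, 10L)
  expect_true(all(lengths(gs1) >= 5 & lengths(gs1) <= 20))
  gs2 <- simulate_genesets(genes, n_terms = 10, size_range = c(5, 20),
                           seed = 4)
  expect_identical(unclass(gs1), unclass(gs2))
  causal <- sample(genes, 10)
  gs3 <- simulate_genesets(genes, n_terms = 5, size_range = c(5, 12),
                           causal_genes = causal, seed = 6)
  expect_true(all(causal %in% gs3[["GO:CAUSAL"]]))
  expect_error(simulate_genesets(genes, size_range = c(5, 200)), "exceeds")
  expect_error(simulate_genesets(genes, size_range = c(2, 10)), "min_size")
})

test_that("datasets are reproducible and written files round-trip", {
  cfg <- sim_config(n_lines = 25, n_genes = 30, architecture = "go_enriched",
                    n_causal = 5, seed = 77)
  ds1 <- simulate_dataset(cfg, n_terms = 6, size_range = c(5, 10))
  ds2 <- simulate_dataset(cfg, n_terms = 6, size_range = c(5, 10))
  expect_identical(ds1$phenotype, ds2$phenotype)
  expect_identical(ds1$true_effects, ds2$true_effects)
  expect_true(all(ds1$causal_genes %in% ds1$genesets[[ds1$config$causal_term]]))
  d <- tempfile()
  write_dataset(ds1, d)
  expr <- read_expression(file.path(d, "expression.tsv"))
  ph <- read_phenotype(file.path(d, "phenotype.tsv"))
  expect_equal(unclass(expr), unclass(ds1$expression), tolerance = 1e-6)
  expect_equal(unname(ph), unname(ds1$phenotype), tolerance = 1e-6)
  gs <- suppressMessages(load_genesets(file.path(d, "genesets.gmt"),
                                       colnames(expr)))
  expect_setequal(names(gs), names(ds1$genesets))
})

test_that("sex pairs share architecture with tunable effect correlation", {
  cfg <- sim_config(n_lines = 60, n_genes = 120, architecture = "sparse",
                    n_causal = 20, target_H2m = 0.8, seed = 91)
  pair1 <- simulate_sex_pair(cfg, rho = 1)
  expect_identical(names(which(pair1$female$true_effects != 0)),
                   names(which(pair1$male$true_effects != 0)))
  expect_equal(pair1$rho_realized, 1, tolerance = 1e-12)
  pair0 <- simulate_sex_pair(cfg, rho = 0.3)
  expect_lt(abs(pair0$rho_realized), 0.9)
  expect_false(identical(unclass(pair0$female$expression),
                         unclass(pair0$male$expression)))
  expect_lt(abs(pair0$male$realized_H2m - 0.8), 0.15)
})
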