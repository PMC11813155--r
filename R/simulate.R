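#' Simulation configuration for synthetic inbred-panel data
#'
#' Collects the knobs of the generator. The trait model works on line means:
#' with genetic variance `sigma_G2`, environmental variance `sigma_E2` and
#' `f` individuals measured per line, the broad-sense heritability of line
#' means is `H2m = sigma_G2 / (sigma_G2 + sigma_E2 / f)`. Either supply
#' `target_H2m` directly, or supply the three components and the target is
#' derived from them.
#'
#' @param n_lines Number of inbred lines (default 200, the panel scale).
#' @param n_genes Number of genes.
#' @param n_factors Latent expression factors inducing gene-gene correlation
#'   (default 10; 0 gives independent genes).
#' @param architecture One of `"dense"`, `"sparse"`, `"go_enriched"`.
#' @param n_causal Number of causal genes (sparse / go_enriched).
#' @param target_H2m Target broad-sense heritability of line means in
#'   `[0, 1)`; default 0.8, the panel-typical value for line means.
#' @param sigma_G2,sigma_E2,f Optional variance components and flies per
#'   line; when all are given they must be consistent with `target_H2m`.
#' @param causal_term Optional term id that must contain the causal genes
#'   (go_enriched).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 200L, n_genes = 1000L, n_factors = 10L,
                       architecture = c("dense", "sparse", "go_enriched"),
                       n_causal = 10L, target_H2m = NULL,
                       sigma_G2 = NULL, sigma_E2 = NULL, f = NULL,
                       causal_term = NULL, seed = 1L) {
  architecture <- match.arg(architecture)
  if (n_lines <= 0L || n_genes <= 0L) stop("nonpositive dimensions")
  if (n_factors < 0L || n_factors >= min(n_lines, n_genes))
    stop("n_factors must lie in [0, min(n_lines, n_genes))")
  comp <- !is.null(sigma_G2) && !is.null(sigma_E2) && !is.null(f)
  if (comp) {
    if (sigma_G2 < 0 || sigma_E2 < 0 || f <= 0) stop("invalid variance components")
    h_comp <- h2m_line_means(sigma_G2, sigma_E2, f)
    if (is.null(target_H2m)) target_H2m <- h_comp
    else if (abs(target_H2m - h_comp) > 1e-8)
      stop("target_H2m inconsistent with sigma_G2/(sigma_G2 + sigma_E2/f)")
  }
  if (is.null(target_H2m)) target_H2m <- 0.8
  if (target_H2m < 0 || target_H2m >= 1)
    stop("target_H2m must lie in [0, 1)")
  if (architecture != "dense" && n_causal > n_genes)
    stop("n_causal exceeds n_genes")
  structure(list(n_lines = as.integer(n_lines), n_genes = as.integer(n_genes),
                 n_factors = as.integer(n_factors),
                 architecture = architecture, n_causal = as.integer(n_causal),
                 target_H2m = target_H2m, sigma_G2 = sigma_G2,
                 sigma_E2 = sigma_E2, f = f, causal_term = causal_term,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Broad-sense heritability of line means
#'
#' `H2m = sigma_G2 / (sigma_G2 + sigma_E2 / f)`: averaging a trait over `f`
#' individuals per inbred line shrinks the environmental variance by `f`,
#' raising the heritability of the analyzed line means.
#'
#' @param sigma_G2 Genetic variance (trait units squared).
#' @param sigma_E2 Environmental variance (trait units squared).
#' @param f Number of individuals measured per line.
#' @return Heritability of line means, a proportion.
#' @export
h2m_line_means <- function(sigma_G2, sigma_E2, f) {
  sigma_G2 / (sigma_G2 + sigma_E2 / f)
}

#' Simulate a lines-by-genes expression matrix
#'
#' Latent-factor model: `X = L F' / sqrt(k) + E` with `L` (`n x k`) and
#' `F` (`m x k`) standard normal and `E` unit-variance noise; the `1/sqrt(k)`
#' scaling keeps the factors at half of each gene's expected variance
#' regardless of `k`, a strong but non-degenerate level of co-expression
#' (unscaled loadings would leave the matrix effectively rank `k`).
#' `k > 0` induces the correlation structure typical of panel
#' transcriptomes; `k = 0` gives independent genes.
#'
#' @param cfg A [sim_config()].
#' @return An [expression_matrix()] with ids `line_001, ...` /
#'   `gene_0001, ...`.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_lines; m <- cfg$n_genes; k <- cfg$n_factors
  set.seed(cfg$seed)
  X <- matrix(rnorm(n * m), n, m)
  if (k > 0L) {
    L <- matrix(rnorm(n * k), n, k)
    F <- matrix(rnorm(m * k), m, k)
    X <- X + tcrossprod(L, F) / sqrt(k)
  }
  expression_matrix(X,
                    line_ids = sprintf("line_%03d", seq_len(n)),
                    gene_ids = sprintf("gene_%04d", seq_len(m)))
}

#' Simulate random gene sets (a synthetic GO collection)
#'
#' Draws `n_terms` random gene sets with sizes uniform in `size_range`.
#' Optionally one designated term is forced to contain a given causal gene
#' list (padded with random genes up to the sampled size).
#'
#' @param gene_ids Universe of gene ids.
#' @param n_terms Number of terms.
#' @param size_range Length-2 integer vector, inclusive size bounds.
#' @param causal_genes Optional character vector that the designated term
#'   must contain.
#' @param causal_term_id Id for the designated term (default `"GO:CAUSAL"`).
#' @param seed Integer seed.
#' @param min_size Size filter applied to the returned collection.
#' @return A `geneset_collection` over `gene_ids`.
#' @export
simulate_genesets <- function(gene_ids, n_terms = 50L, size_range = c(5L, 20L),
                              causal_genes = NULL,
                              causal_term_id = "GO:CAUSAL", seed = 1L,
                              min_size = 5L) {
  if (size_range[1] < min_size) stop("size_range minimum below min_size")
  if (size_range[2] > length(gene_ids)) stop("size_range maximum exceeds n_genes")
  set.seed(seed)
  sizes <- sample(seq.int(size_range[1], size_range[2]), n_terms, replace = TRUE)
  sets <- lapply(seq_len(n_terms), function(i) sample(gene_ids, sizes[i]))
  names(sets) <- sprintf("GO:%07d", seq_len(n_terms))
  if (!is.null(causal_genes)) {
    stopifnot(all(causal_genes %in% gene_ids))
    sz <- max(length(causal_genes), sizes[1])
    pad <- sample(setdiff(gene_ids, causal_genes), sz - length(causal_genes))
    sets[[1]] <- c(causal_genes, pad)
    names(sets)[1] <- causal_term_id
  }
  load_genesets(sets, universe = gene_ids, min_size = min_size)
}

#' Simulate a line-mean trait over an expression matrix
#'
#' Gene effects are drawn on the standardized expression scale: all genes
#' for a dense architecture, a random `n_causal` subset for sparse, and a
#' subset of the designated term's members for go_enriched. Genetic values
#' are `g = W beta`; line-level residual noise is calibrated so that
#' `Var(g) / (Var(g) + sigma_e_line^2)` equals the target heritability of
#' line means, with `sigma_e_line^2 = sigma_E2 / f` when components are
#' supplied.
#'
#' @param expr An [expression_matrix()].
#' @param cfg A [sim_config()].
#' @param genesets Optional `geneset_collection`; required for go_enriched
#'   (the causal term must exist in it).
#' @return Object of class `sim_dataset`: list with `expression`,
#'   `phenotype` (named vector), `genesets`, `true_effects` (per retained
#'   gene, standardized scale), `true_genetic_values`, `realized_H2m`,
#'   `causal_genes`, `config`.
#' @export
simulate_trait <- function(expr, cfg, genesets = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  W <- suppressWarnings(standardize_expression(expr))
  genes <- colnames(W)
  m <- length(genes); n <- nrow(W)
  set.seed(cfg$seed + 1L)
  causal <- switch(cfg$architecture,
    dense = genes,
    sparse = sample(genes, cfg$n_causal),
    go_enriched = {
      if (is.null(genesets) || is.null(cfg$causal_term) ||
          !cfg$causal_term %in% names(genesets))
        stop("go_enriched needs a genesets collection containing causal_term")
      members <- intersect(genesets[[cfg$causal_term]], genes)
      if (length(members) < cfg$n_causal)
        stop("causal term has fewer members than n_causal")
      sample(members, cfg$n_causal)
    })
  beta <- stats::setNames(numeric(m), genes)
  h2 <- cfg$target_H2m
  if (h2 > 0) {
    beta[causal] <- rnorm(length(causal)) / sqrt(length(causal))
    g <- drop(W %*% beta)
    if (!is.null(cfg$sigma_G2)) {
      # scale genetic values to the stated genetic variance exactly
      sc <- sqrt(cfg$sigma_G2 / stats::var(g))
      beta <- beta * sc
      g <- g * sc
      sigma_line2 <- cfg$sigma_E2 / cfg$f
    } else {
      sigma_line2 <- stats::var(g) * (1 - h2) / h2
    }
  } else {
    g <- numeric(n)
    sigma_line2 <- if (!is.null(cfg$sigma_E2)) cfg$sigma_E2 / cfg$f else 1
  }
  e <- rnorm(n, sd = sqrt(sigma_line2))
  y <- stats::setNames(g + e, rownames(W))
  realized <- if (h2 > 0) stats::var(g) / (stats::var(g) + stats::var(e)) else 0
  structure(list(expression = expr, phenotype = y, genesets = genesets,
                 true_effects = beta, true_genetic_values = g,
                 realized_H2m = realized,
                 causal_genes = if (h2 > 0) causal else character(0),
                 config = cfg),
            class = "sim_dataset")
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: expression, gene sets (with the causal term when the
#' architecture is go_enriched), and trait in one call.
#'
#' @param cfg A [sim_config()].
#' @param n_terms,size_range Passed to [simulate_genesets()].
#' @return A `sim_dataset` (see [simulate_trait()]).
#' @export
simulate_dataset <- function(cfg, n_terms = 50L, size_range = c(5L, 20L)) {
  expr <- simulate_expression(cfg)
  causal_genes <- NULL
  if (cfg$architecture == "go_enriched") {
    set.seed(cfg$seed + 2L)
    causal_genes <- sample(colnames(expr), cfg$n_causal)
    if (is.null(cfg$causal_term)) cfg$causal_term <- "GO:CAUSAL"
  }
  gs <- simulate_genesets(colnames(expr), n_terms = n_terms,
                          size_range = size_range,
                          causal_genes = causal_genes,
                          causal_term_id = if (is.null(cfg$causal_term))
                            "GO:CAUSAL" else cfg$causal_term,
                          seed = cfg$seed + 3L)
  simulate_trait(expr, cfg, genesets = gs)
}

#' Simulate a male/female dataset pair with a shared genetic architecture
#'
#' Panels are typically analyzed per sex: expression is sex-specific, but
#' gene effects are genetically correlated across sexes. This generates two
#' independent expression matrices and draws the two effect vectors with
#' correlation `rho` on the shared causal gene set (`rho = 1`, the default,
#' reproduces identical effects, the limit appropriate for traits with
#' little sexual dimorphism; lower values emulate dimorphic traits).
#'
#' @param cfg A [sim_config()]; each sex uses a seed offset derived from
#'   `cfg$seed`.
#' @param rho Cross-sex effect correlation in `[-1, 1]`.
#' @return List with `sim_dataset` elements `female` and `male` and the
#'   realized cross-sex effect correlation `rho_realized`.
#' @export
simulate_sex_pair <- function(cfg, rho = 1) {
  stopifnot(inherits(cfg, "sim_config"), abs(rho) <= 1)
  cfg_f <- cfg
  cfg_m <- cfg
  cfg_m$seed <- cfg$seed + 100000L
  f <- simulate_trait(simulate_expression(cfg_f), cfg_f,
                      genesets = NULL)
  m <- simulate_trait(simulate_expression(cfg_m), cfg_m,
                      genesets = NULL)
  # re-draw the male effects as rho * female + sqrt(1-rho^2) * independent,
  # on the shared causal set, then rebuild the male phenotype
  set.seed(cfg$seed + 200000L)
  causal <- f$causal_genes
  beta_m <- f$true_effects
  if (length(causal)) {
    noise <- stats::setNames(rnorm(length(causal)) / sqrt(length(causal)),
                             causal)
    beta_m[causal] <- rho * f$true_effects[causal] +
      sqrt(1 - rho^2) * noise
  }
  Wm <- suppressWarnings(standardize_expression(m$expression))
  g <- drop(Wm %*% beta_m[colnames(Wm)])
  h2 <- cfg$target_H2m
  sigma_line2 <- if (h2 > 0) stats::var(g) * (1 - h2) / h2 else 1
  e <- rnorm(nrow(Wm), sd = sqrt(max(sigma_line2, 1e-12)))
  m$true_effects <- beta_m
  m$true_genetic_values <- g
  m$phenotype <- stats::setNames(g + e, rownames(Wm))
  m$realized_H2m <- if (h2 > 0) stats::var(g) / (stats::var(g) + stats::var(e)) else 0
  rho_real <- if (length(causal) > 1)
    cor(f$true_effects[causal], beta_m[causal]) else NA_real_
  list(female = f, male = m, rho_realized = rho_real)
}

#' Write a simulated dataset to disk
#'
#' Emits the package's external formats: `expression.tsv` (first column
#' `line_id`), `phenotype.tsv` (`line_id`, `value`), `genesets.gmt`, and
#' `truth.tsv` (`gene_id`, `true_effect`).
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_expr <- file.path(dir, "expression.tsv")
  df <- data.frame(line_id = rownames(ds$expression),
                   unclass(ds$expression), check.names = FALSE)
  write.table(df, p_expr, sep = "\t", quote = FALSE, row.names = FALSE)
  p_ph <- file.path(dir, "phenotype.tsv")
  write.table(data.frame(line_id = names(ds$phenotype),
                         value = unname(ds$phenotype)),
              p_ph, sep = "\t", quote = FALSE, row.names = FALSE)
  p_gmt <- file.path(dir, "genesets.gmt")
  if (!is.null(ds$genesets)) {
    lines <- vapply(names(ds$genesets), function(id)
      paste(c(id, "simulated", ds$genesets[[id]]), collapse = "\t"),
      character(1))
    writeLines(lines, p_gmt)
  }
  p_truth <- file.path(dir, "truth.tsv")
  write.table(data.frame(gene_id = names(ds$true_effects),
                         true_effect = unname(ds$true_effects)),
              p_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p_expr, p_ph, p_gmt, p_truth))
}
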