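test_that("standardization centers, scales, excludes constants, and is idempotent", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  W <- suppressWarnings(standardize_expression(X))
  # sample sd of (1,2,3) is exactly 1
  expect_equal(unname(W[, "a"]), c(-1, 0, 1))
  expect_equal(attr(W, "excluded_genes"), "b")
  expect_false("b" %in% colnames(W))
  expect_true(all(abs(colMeans(W)) <= 1e-10))
  expect_true(all(abs(apply(W, 2, var) - 1) <= 1e-8))
  W2 <- standardize_expression(W)
  expect_equal(unclass(W2), unclass(W), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(standardize_expression(cbind(rep(1, 5), rep(2, 5))),
               "no variable genes")
})

test_that("TRM matches the outer-product form and its trace identity", {
  w <- matrix(c(-1, 0, 1), 3, 1)
  T1 <- build_trm(w)
  expect_equal(unclass(T1),
               matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3),
               ignore_attr = TRUE)
  set.seed(42)
  for (dims in list(c(10, 4), c(25, 40))) {
    X <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    colnames(X) <- paste0("g", seq_len(dims[2]))
    W <- standardize_expression(X)
    T <- build_trm(W)
    # each standardized column contributes (n-1)/m to the trace
    expect_equal(sum(diag(T)), dims[1] - 1, tolerance = 1e-6)
    expect_equal(unclass(T), unclass(t(T)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_gte(min(eigen(T, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    # invariant to gene column order
    perm <- sample(ncol(W))
    expect_equal(unclass(build_trm(W[, perm])), unclass(T),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("TRM decomposes over gene blocks", {
  set.seed(7)
  X <- matrix(rnorm(20 * 30), 20, 30)
  colnames(X) <- paste0("g", 1:30)
  W <- standardize_expression(X)
  members <- paste0("g", c(2, 5, 9, 11, 25))
  blocks <- partition_genes(W, members)
  mA <- ncol(blocks$in_set); mB <- ncol(blocks$out_set)
  TA <- build_trm(blocks$in_set); TB <- build_trm(blocks$out_set)
  T <- build_trm(W)
  expect_equal((mA * unclass(TA) + mB * unclass(TB)) / (mA + mB),
               unclass(T), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("gene partition preserves order, counts, and round-trips", {
  X <- matrix(seq_len(20), 4, 5)
  colnames(X) <- paste0("g", 1:5)
  p <- partition_genes(X, c("g2", "g4"))
  expect_equal(colnames(p$in_set), c("g2", "g4"))
  expect_equal(colnames(p$out_set), c("g1", "g3", "g5"))
  expect_equal(ncol(p$in_set) + ncol(p$out_set), 5L)
  reassembled <- cbind(p$in_set, p$out_set)[, colnames(X)]
  expect_identical(reassembled, X)
  # all genes in the set: empty complement, and an empty block errors
  expect_equal(ncol(partition_genes(X, paste0("g", 1:5))$out_set), 0L)
  expect_error(partition_genes(X, "nope"), "absent")
})

test_that("gene-set loading filters by universe and size, deduplicates", {
  universe <- paste0("g", 1:20)
  sets <- list(A = paste0("g", 1:4),          # effective size 4
               B = paste0("g", c(1:5, 5)),    # duplicate member, size 5
               C = paste0("g", 3:8),          # size 6
               D = paste0("x", 1:6))          # fully outside the universe
  path <- write_toy_gmt(sets)
  gs <- suppressMessages(load_genesets(path, universe, min_size = 5))
  expect_equal(sort(names(gs)), c("B", "C"))
  expect_equal(gs$B, paste0("g", 1:5))
  # retained count is monotone non-increasing in min_size
  counts <- vapply(3:7, function(ms)
    length(suppressMessages(load_genesets(path, universe, min_size = ms))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
  dup_path <- tempfile(fileext = ".gmt")
  writeLines(c("A\td\tg1\tg2\tg3", "A\td\tg4\tg5\tg6"), dup_path)
  expect_error(load_genesets(dup_path, universe), "duplicate")
  bad_path <- tempfile(fileext = ".gmt")
  writeLines(c("A\td\tg1\tg2", "B\tonlytwo"), bad_path)
  expect_error(read_gmt(bad_path), "line 2")
})

test_that("expression/phenotype I/O round-trips and aligns by line id", {
  set.seed(3)
  X <- matrix(rnorm(12), 4, 3)
  expr <- expression_matrix(X, paste0("L", 1:4), paste0("g", 1:3))
  y <- stats::setNames(rnorm(5), paste0("L", c(4, 2, 1, 3, 9)))
  d <- tempfile(); dir.create(d)
  df <- data.frame(line_id = rownames(expr), unclass(expr),
                   check.names = FALSE)
  write.table(df, file.path(d, "e.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expr2 <- read_expression(file.path(d, "e.tsv"))
  expect_equal(unclass(expr2), unclass(expr), tolerance = 1e-12)
  expect_error(align_lines(expr2, y), "unmatched")
  al <- suppressMessages(align_lines(expr2, y, drop_unmatched = TRUE))
  expect_identical(rownames(al$expr), names(al$pheno))
  expect_equal(al$pheno[["L2"]], y[["L2"]])
})
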