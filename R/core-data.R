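#' Construct an expression matrix
#'
#' Bundles a lines-by-genes matrix of expression values with unique line and
#' gene identifiers. This is the common input container for every prediction
#' model in the package.
#'
#' @param values Numeric matrix, `n` lines by `m` genes. No missing values.
#' @param line_ids Character vector of unique line identifiers (length `n`).
#' @param gene_ids Character vector of unique gene identifiers (length `m`).
#' @return An object of class `expression_matrix` (a numeric matrix with
#'   `dimnames` set and validated identifiers).
#' @export
expression_matrix <- function(values, line_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(line_ids) || is.null(gene_ids))
    stop("line_ids and gene_ids are required")
  line_ids <- as.character(line_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) < 2L) stop("need at least 2 lines")
  if (ncol(values) < 1L) stop("need at least 1 gene")
  if (length(line_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(line_ids)) stop("duplicate line_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyNA(values)) stop("missing values in expression matrix")
  dimnames(values) <- list(line_ids, gene_ids)
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' Read a lines-by-genes expression table
#'
#' Expects a UTF-8 TSV whose first column is `line_id` and whose remaining
#' columns are gene identifiers; cells are numeric with no missing values.
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "line_id") stop("first column must be 'line_id'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  expression_matrix(vals, line_ids = df$line_id, gene_ids = colnames(vals))
}

#' Read a per-line phenotype table
#'
#' Expects a TSV with columns `line_id` and `value` (one trait, line means).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of trait values, names are line ids.
#' @export
read_phenotype <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("line_id", "value") %in% names(df)))
    stop("phenotype table needs columns 'line_id' and 'value'")
  if (anyNA(df$value)) stop("missing phenotype values")
  if (anyDuplicated(df$line_id)) stop("duplicate line_ids in phenotype")
  y <- as.numeric(df$value)
  names(y) <- as.character(df$line_id)
  y
}

#' Align expression and phenotype by line id
#'
#' Joins the two inputs on line identifiers and returns them in matched order.
#' By default any line present in one input but not the other is an error;
#' with `drop_unmatched = TRUE` unmatched lines are dropped with a message
#' (mirroring removal of lines with missing measurements).
#'
#' @param expr An [expression_matrix()].
#' @param pheno Named numeric vector from [read_phenotype()].
#' @param drop_unmatched Drop (rather than error on) unmatched lines.
#' @return List with elements `expr` and `pheno`, aligned.
#' @export
align_lines <- function(expr, pheno, drop_unmatched = FALSE) {
  common <- intersect(rownames(expr), names(pheno))
  if (length(common) < 2L) stop("fewer than 2 lines in common")
  n_drop <- (nrow(expr) - length(common)) + (length(pheno) - length(common))
  if (n_drop > 0L) {
    if (!drop_unmatched)
      stop(sprintf("%d unmatched line(s); set drop_unmatched = TRUE to drop", n_drop))
    message(sprintf("dropping %d unmatched line(s)", n_drop))
  }
  list(expr = expression_matrix(expr[common, , drop = FALSE]),
       pheno = pheno[common])
}

#' Column-standardize an expression matrix
#'
#' Centers every gene to mean zero and scales to unit sample variance
#' (denominator `n - 1`). Genes with zero variance cannot be scaled and are
#' excluded with a warning; they are reported in the `excluded_genes`
#' attribute rather than kept silently.
#'
#' @param expr Numeric matrix, lines by genes (an [expression_matrix()] or
#'   plain matrix).
#' @return Numeric matrix of class `standardized_expression` with attribute
#'   `excluded_genes` (character vector, possibly empty).
#' @export
standardize_expression <- function(expr) {
  X <- unclass(as.matrix(expr))
  if (nrow(X) < 3L) stop("need at least 3 lines to standardize")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  keep <- s > 0
  if (!any(keep)) stop("no variable genes")
  excluded <- colnames(X)[!keep]
  if (length(excluded))
    warning(sprintf("excluding %d zero-variance gene(s)", length(excluded)))
  W <- sweep(Xc[, keep, drop = FALSE], 2L, s[keep], "/")
  attr(W, "excluded_genes") <- excluded
  class(W) <- c("standardized_expression", "matrix", "array")
  W
}

#' Center columns of a matrix (and optionally a response)
#'
#' @param X Numeric matrix.
#' @return Matrix with column means subtracted; means kept in attribute
#'   `col_means`.
#' @export
center_columns <- function(X) {
  X <- unclass(as.matrix(X))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  attr(Xc, "col_means") <- mu
  Xc
}

#' Transcriptomic relationship matrix
#'
#' Builds the kernel `T = W W' / m` from a standardized expression matrix
#' `W`: the transcriptomic analogue of a genomic relationship matrix. For a
#' fully standardized `W` (unit sample variance per gene), `trace(T) = n - 1`
#' exactly.
#'
#' @param W Standardized expression matrix ([standardize_expression()]).
#' @param scale_m Number of genes to divide by; defaults to `ncol(W)`.
#'   Passing the total gene count of a larger matrix lets block kernels share
#'   a common scale.
#' @return An `n x n` matrix of class `trm` with attribute `scale_m`.
#' @export
build_trm <- function(W, scale_m = ncol(W)) {
  W <- unclass(as.matrix(W))
  if (ncol(W) == 0L) stop("no genes: cannot build a relationship matrix")
  if (scale_m <= 0) stop("scale_m must be positive")
  T <- tcrossprod(W) / scale_m
  T <- (T + t(T)) / 2
  attr(T, "scale_m") <- as.integer(scale_m)
  class(T) <- c("trm", "matrix", "array")
  T
}

#' Split an expression matrix by gene-set membership
#'
#' Partitions the columns of `expr` into the block inside a gene set (GO
#' term) and the complementary block, preserving the original column order
#' within each block.
#'
#' @param expr Lines-by-genes numeric matrix with gene ids as column names.
#' @param members Character vector of member gene ids.
#' @return List with matrices `in_set` and `out_set`.
#' @export
partition_genes <- function(expr, members) {
  X <- as.matrix(expr)
  genes <- colnames(X)
  if (is.null(genes)) stop("expression matrix must have gene ids")
  extra <- setdiff(members, genes)
  if (length(extra))
    stop(sprintf("%d member gene(s) absent from the expression universe", length(extra)))
  inside <- genes %in% members
  if (!any(inside)) stop("empty GO block")
  list(in_set = X[, inside, drop = FALSE],
       out_set = X[, !inside, drop = FALSE])
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (term id -> member gene ids),
#'   with a parallel `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    ids[i] <- f[1]
    desc[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(ids))
    stop("duplicate term ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(desc, ids)
  sets
}

#' Load and filter a gene-set collection
#'
#' Reads gene sets (from a GMT path or an already-parsed named list),
#' restricts each set to the expression gene universe, deduplicates
#' membership, and drops sets with fewer than `min_size` members present in
#' the universe. The size filter mirrors the usual requirement that a GO
#' term have at least five annotated genes in the expression data.
#'
#' @param x Path to a GMT file, or a named list of character vectors.
#' @param universe Character vector of gene ids present in the expression
#'   data.
#' @param min_size Minimum retained set size (default 5).
#' @return Object of class `geneset_collection`: a named list of member
#'   vectors with attributes `min_size`, `n_input`, `n_dropped`.
#' @export
load_genesets <- function(x, universe, min_size = 5L) {
  sets <- if (is.character(x) && length(x) == 1L) read_gmt(x) else x
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique term ids")
  restricted <- lapply(sets, function(g) unique(g[g %in% universe]))
  keep <- vapply(restricted, length, integer(1)) >= min_size
  dropped <- sum(!keep)
  if (dropped)
    message(sprintf("dropped %d set(s) with < %d genes in the universe",
                    dropped, min_size))
  out <- restricted[keep]
  attributes(out) <- list(names = names(restricted)[keep],
                          min_size = as.integer(min_size),
                          n_input = length(sets),
                          n_dropped = dropped)
  class(out) <- "geneset_collection"
  out
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d set(s) (min size %d; %d dropped of %d input)\n",
              length(x), attr(x, "min_size"), attr(x, "n_dropped"),
              attr(x, "n_input")))
  invisible(x)
}
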