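# Small reusable fixtures, all generated in code under fixed seeds.

toy_xy <- function(n = 40, m = 5, beta = NULL, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  colnames(X) <- sprintf("g%02d", seq_len(m))
  if (is.null(beta)) beta <- c(1, -1, rep(0, m - 2))
  y <- drop(X %*% beta) + rnorm(n, sd = sd)
  Xc <- center_columns(X)
  list(X = unclass(Xc), y = y - mean(y), beta = beta)
}

# A tiny GMT file written to a temp path.
write_toy_gmt <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(id)
    paste(c(id, "desc", sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}
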