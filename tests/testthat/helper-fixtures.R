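# In-memory fixtures shared across test files.

toy_matrix <- function(values, samples = NULL, genes = NULL,
                       conditions = NULL, scale = "log2cpm") {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("G%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  ann <- data.frame(sample_id = colnames(m),
                    condition = conditions %||% rep("c1", ncol(m)),
                    stringsAsFactors = FALSE)
  ExpressionMatrix(m, ann, scale = scale)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Independent enumeration oracle for the upper-tail hypergeometric:
# P(overlap >= k) summed term by term from binomial coefficients.
hyper_enum <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# Brute-force step-up BH from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

default_fixture <- function() {
  truth <- simulation_truth()
  list(truth = truth, expr = simulate_coculture(truth))
}
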