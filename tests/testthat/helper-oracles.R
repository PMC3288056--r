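# Independent oracles and small fixture builders shared across tests.

# Upper-tail hypergeometric P(X >= k) by direct summation of point masses
# (log-binomials via lchoose; independent of phyper).
oracle_hyper_tail <- function(k, K, n, N) {
  jmax <- min(n, K)
  if (k > jmax) return(0)
  j <- max(k, 0):jmax
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Quadratic brute-force Benjamini-Hochberg: adj_i = min over terms with
# rank >= rank_i of p_j * M / rank_j, capped at 1.
oracle_bh <- function(p) {
  M <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(M), function(i) {
    min(1, min((p * M / r)[r >= r[i]]))
  }, 0)
}

# Random well-formed count table.
random_table <- function(n, seed) {
  set.seed(seed)
  spectral_count_table(
    protein_id = sprintf("p%03d", seq_len(n)),
    symbol = sprintf("Sym%03d", seq_len(n)),
    gcp = rpois(n, 50), laminin = rpois(n, 5), hss = rpois(n, 30))
}

write_counts_tsv <- function(table, path = tempfile(fileext = ".tsv")) {
  write.table(as.data.frame(table)[, c("protein_id", "symbol", "gcp",
                                       "laminin", "hss")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gmt_file <- function(terms, path = tempfile(fileext = ".gmt")) {
  writeLines(vapply(terms, function(t)
    paste(c(t$term_id, t$term_name, t$members), collapse = "\t"), ""),
    path)
  path
}
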