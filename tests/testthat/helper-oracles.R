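# Independent brute-force oracles used to check the implementation. These are
# deliberately naive re-derivations, kept free of any package internals.

# position-by-position overlapping word count, N never matches
oracle_count_word <- function(seq, word) {
  seq <- toupper(seq); word <- toupper(word)
  L <- nchar(seq); w <- nchar(word)
  if (L < w) return(0L)
  hits <- 0L
  for (i in seq_len(L - w + 1L)) {
    if (substr(seq, i, i + w - 1L) == word) hits <- hits + 1L
  }
  hits
}

# Benjamini-Hochberg step-up, re-derived from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# empirical detection p per probe against a pooled negative-control null
oracle_detection_p <- function(probe_means, nc_values) {
  vapply(probe_means, function(m) sum(nc_values >= m) / length(nc_values), numeric(1))
}

# exhaustive hypergeometric tails: enumerate every size-n leading set of a
# small universe and count carrier totals
oracle_hyper_tails <- function(carrier, n, x) {
  N <- length(carrier)
  sets <- utils::combn(N, n)
  counts <- apply(sets, 2, function(idx) sum(carrier[idx]))
  c(enrich = mean(counts >= x), deplete = mean(counts <= x))
}

# CPDV by direct definition, one bin at a time
oracle_cpdv <- function(values, lookahead = 5) {
  n <- length(values)
  vapply(seq_len(n), function(i) {
    if (i == n) return(-Inf)
    values[i] - min(values[(i + 1):min(i + lookahead, n)])
  }, numeric(1))
}

# random DNA with optional N bases
random_dna <- function(len, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}
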