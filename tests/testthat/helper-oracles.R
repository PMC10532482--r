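# Independent test oracles, deliberately written without reusing package
# internals.

# plain Needleman-Wunsch edit distance (match 0 / sub 1 / indel 1)
nw_edit <- function(a, b) {
  va <- strsplit(a, "")[[1L]]
  vb <- strsplit(b, "")[[1L]]
  n <- length(va)
  m <- length(vb)
  d <- matrix(0, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j] + (va[i] != vb[j]),
                               d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L)
    }
  }
  d[n + 1L, m + 1L]
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# random valid dot-bracket string via random folding of a random sequence
random_dotbracket <- function(n) {
  fold_mfe(random_rna(n))$dotbracket
}

# distance matrix of squared Euclidean point configurations (guaranteed
# Euclidean input for the metric-scaling identities)
random_euclidean_dist <- function(n, d = 3, labels = paste0("t", seq_len(n))) {
  pts <- matrix(rnorm(n * d), n)
  its2_dist(as.matrix(stats::dist(pts)), labels)
}

partition_labels <- function(partition, ids) {
  out <- rep(NA_integer_, length(ids))
  for (g in seq_along(partition)) {
    out[match(partition[[g]], ids)] <- g
  }
  out
}
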