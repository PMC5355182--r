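# Shared helpers: random matrices and independent brute-force oracles.

rand_accession_matrix <- function(n, m, B = 3L, presence = NULL) {
  z <- matrix(sample(0:B, n * m, replace = TRUE), n, m)
  if (!is.null(presence)) {
    # sparser matrices for cover instances: each cell present w.p. `presence`
    z <- matrix(ifelse(stats::runif(n * m) < presence,
                       sample(1:B, n * m, replace = TRUE), 0L), n, m)
  }
  rownames(z) <- sprintf("A%03d", seq_len(n))
  colnames(z) <- sprintf("SSR%02d_%03d", rep(seq_len(max(1, m %/% 5 + 1)),
                                             each = 5, length.out = m),
                         seq_len(m))
  accession_matrix(z, B)
}

# Explicit double-loop recomputation of the rareness coefficient.
rareness_oracle <- function(z) {
  n <- nrow(z); m <- ncol(z)
  R <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(m)) {
      zbar <- sum(z[, j]) / n
      s <- s + (z[i, j] - zbar)^2
    }
    R[i] <- s / m
  }
  R
}

# Independent Welch t-statistic from the textbook formula.
welch_oracle <- function(x, y) {
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  (mean(x) - mean(y)) / sqrt(se2)
}

# 2 N x mutual information (nats) of the empirical joint of a table.
mutual_information_g <- function(tab) {
  N <- sum(tab)
  p <- tab / N
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  2 * N * mi
}

f1 <- function() make_fixture("F1")
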