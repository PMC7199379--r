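# Independent oracles used across the suite. These deliberately take the
# slow, direct route (expanded data, pairwise distances, term-by-term
# expectations) so they share no code with the package implementations.

# |Pearson correlation| computed from first principles on raw vectors.
abs_pearson_oracle <- function(x, y) {
  n <- length(x)
  cv <- mean(x * y) - mean(x) * mean(y)
  abs(cv) / sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
}

# Population trend correlation by term-by-term expansion of the joint
# expectations over the K x 2 cell probabilities.
tc_expectation_oracle <- function(probs, scores) {
  ex <- 0; ey <- 0
  for (k in seq_along(scores)) for (m in 1:2) {
    ex <- ex + scores[k] * probs[k, m]
    ey <- ey + (m - 1) * probs[k, m]
  }
  num <- 0; vx <- 0; vy <- 0
  for (k in seq_along(scores)) for (m in 1:2) {
    num <- num + (scores[k] - ex) * ((m - 1) - ey) * probs[k, m]
    vx <- vx + (scores[k] - ex)^2 * probs[k, m]
    vy <- vy + ((m - 1) - ey)^2 * probs[k, m]
  }
  abs(num) / sqrt(vx * vy)
}

# Naive O(n^2) double-centering distance correlation (V-statistic).
dcor_naive_oracle <- function(x, y) {
  A <- as.matrix(dist(x))
  B <- as.matrix(dist(y))
  Ac <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
  Bc <- B - rowMeans(B)[row(B)] - colMeans(B)[col(B)] + mean(B)
  dcov2 <- mean(Ac * Bc)
  sqrt(dcov2 / sqrt(mean(Ac^2) * mean(Bc^2)))
}

# Cell-by-cell (O - E)^2 / E chi-squared statistic.
chisq_oracle <- function(counts) {
  n <- sum(counts)
  tot <- 0
  for (k in seq_len(nrow(counts))) for (m in seq_len(ncol(counts))) {
    e <- sum(counts[k, ]) * sum(counts[, m]) / n
    if (e > 0) tot <- tot + (counts[k, m] - e)^2 / e
  }
  tot
}

# Grow-prefix scan: smallest d such that all true features are in the
# top-d of the ranking.
prefix_cover_oracle <- function(ranking, true_set) {
  for (d in seq_along(ranking)) {
    if (all(true_set %in% ranking[seq_len(d)])) return(d)
  }
  NA_integer_
}

# Expand a K x 2 count table into raw (x, y) vectors.
expand_table <- function(counts, scores) {
  x <- rep(rep(scores, 2L), as.vector(counts))
  y <- rep(rep(0:1, each = nrow(counts)), as.vector(counts))
  list(x = x, y = y)
}

# Random K x 2 count table with non-degenerate margins.
random_table <- function(K = 3L, n = 80L) {
  repeat {
    counts <- matrix(rmultinom(1L, n, prob = runif(2L * K, 0.2, 1)), nrow = K)
    if (all(colSums(counts) > 0) && sum(rowSums(counts) > 0) >= 2L) return(counts)
  }
}
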