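# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's own computational paths: explicit loops
# and textbook formulas only.

# Random strictly positive compositions (log-normal parts, closed rows).
rand_comp <- function(n, q) {
  closure(matrix(exp(rnorm(n * q, sd = 1)), n, q))
}

# Brute-force kernel distance covariance: elementwise double centering by
# explicit row/column/grand means, then the normalized inner product.
kdc_oracle <- function(K, L) {
  n <- nrow(K)
  cen <- function(M) {
    out <- matrix(0, n, n)
    gm <- mean(M)
    for (i in seq_len(n)) for (j in seq_len(n))
      out[i, j] <- M[i, j] - mean(M[i, ]) - mean(M[, j]) + gm
    out
  }
  sum(cen(K) * cen(L)) / n^2
}

# Aitchison distance via the double-sum over all log-ratio pairs.
ad_doublesum_oracle <- function(P) {
  n <- nrow(P); q <- ncol(P)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (r in seq_len(q)) for (s in seq_len(q))
      acc <- acc + (log(P[i, r] / P[i, s]) - log(P[j, r] / P[j, s]))^2
    D[i, j] <- sqrt(acc / (2 * q))
  }
  D
}

# Squared distance correlation of Szekely, Rizzo and Bakirov, computed
# directly from doubly centered Euclidean distance matrices.
szekely_dcor2 <- function(x, y) {
  a <- as.matrix(dist(as.matrix(x)))
  b <- as.matrix(dist(as.matrix(y)))
  cen <- function(M) sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + mean(M)
  A <- cen(a); B <- cen(b)
  mean(A * B) / sqrt(mean(A * A) * mean(B * B))
}

# Minimal two-group overdispersed multinomial generator for unit tests that
# need something cheaper/simpler than the full simulator.
tiny_two_group <- function(n_per_group, probs0, probs1, total = 5000,
                           olre_sd = 0.2) {
  x <- rep(0:1, each = n_per_group)
  counts <- t(vapply(x, function(g) {
    p <- if (g == 1) probs1 else probs0
    eta <- log(p) + rnorm(length(p), 0, olre_sd)
    pr <- exp(eta - max(eta))
    drop(rmultinom(1, total, pr))
  }, numeric(length(probs0))))
  colnames(counts) <- paste0("C", seq_along(probs0))
  list(counts = counts, x = x)
}
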