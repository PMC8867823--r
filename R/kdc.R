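# The kernel distance covariance statistic, its normalized (distance
# correlation) form, and the permutation test.

#' Kernel distance covariance statistic
#'
#' `KDC_n = trace(K H L H) / n^2`, with `H = I - 11'/n`. Computed as the
#' Frobenius inner product of the doubly centered `K` with `L`, which is
#' identical to the trace form and costs O(n^2).
#'
#' @param K,L n x n kernel matrices (composition side and predictor side).
#' @return The statistic (a nonnegative number when both kernels are PSD).
#' @export
kdc_statistic <- function(K, L) {
  K <- as.matrix(K); L <- as.matrix(L)
  if (!all(dim(K) == dim(L))) stop("'K' and 'L' must have matching dimensions")
  n <- nrow(K)
  sum(double_center(K) * L) / n^2
}

#' Distance correlation effect size
#'
#' The normalized kernel distance covariance
#' `KDC(K, L) / sqrt(KDC(K, K) * KDC(L, L))`, lying in \[0, 1\] for positive
#' semidefinite kernels. When both kernels are L2-distance kernels
#' (`dist_kernel(..., squared = FALSE)`) this equals the squared distance
#' correlation of Szekely, Rizzo and Bakirov.
#'
#' @param K,L n x n kernel matrices.
#' @return The distance correlation (dimensionless).
#' @export
kdc_dcor <- function(K, L) {
  K <- as.matrix(K); L <- as.matrix(L)
  if (!all(dim(K) == dim(L))) stop("'K' and 'L' must have matching dimensions")
  Kc <- double_center(K)
  Lc <- double_center(L)
  sxx <- sum(Kc * Kc)
  syy <- sum(Lc * Lc)
  eps <- .Machine$double.eps * nrow(K)^2
  if (sxx <= eps) stop("degenerate composition kernel (constant after centering)")
  if (syy <= eps) stop("degenerate predictor kernel (constant after centering)")
  sum(Kc * Lc) / sqrt(sxx * syy)
}

# Enumerate all permutations of 1..n (used only when n! is small).
perm_enumerate <- function(n) {
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], rec(v[-i]), deparse.level = 0L)))
  }
  rec(seq_len(n))
}

# Draw B permutations of 1..n (rows of the returned matrix), within strata
# when supplied. Exact enumeration replaces sampling when n! <= `exact_max`
# and there are no strata.
draw_permutations <- function(n, B, strata = NULL, seed = NULL,
                              exact_max = 10000) {
  if (is.null(strata) && factorial(n) <= exact_max) {
    return(list(idx = perm_enumerate(n), exact = TRUE))
  }
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    groups <- split(seq_len(n), strata)
  }
  idx <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      if (is.null(strata)) return(sample.int(n))
      p <- seq_len(n)
      for (g in groups) if (length(g) > 1L) p[g] <- g[sample.int(length(g))]
      p
    }, integer(n)))
  })
  list(idx = idx, exact = FALSE)
}

#' Permutation test for the kernel distance covariance statistic
#'
#' Jointly permutes the rows and columns of the predictor kernel `L` and
#' recomputes the statistic. Sampled permutations use the add-one p-value
#' `(1 + #permuted >= observed) / (B + 1)`, which keeps the test valid at
#' every level; ties count toward the numerator. When `n! <= 10000` and no
#' strata are given, all permutations are enumerated and the p-value is
#' exact. With `strata`, permutations are restricted within strata.
#'
#' @param K,L Kernel matrices.
#' @param B Number of sampled permutations (default 10000).
#' @param seed Optional integer seed; results are reproducible given it.
#' @param strata Optional categorical labels restricting the permutations.
#' @return A list with `statistic`, `dcor`, `p.value`, `n_perm`, `exact`,
#'   `perm_stats` and `seed`.
#' @export
kdc_perm_test <- function(K, L, B = 10000, seed = NULL, strata = NULL) {
  K <- as.matrix(K); L <- as.matrix(L)
  n <- nrow(K)
  if (n < 3L) stop("permutation test needs at least 3 samples")
  if (!all(dim(K) == dim(L))) stop("'K' and 'L' must have matching dimensions")
  if (B < 1L) stop("'B' must be at least 1")
  Kc <- double_center(K)
  obs <- sum(Kc * L) / n^2
  perms <- draw_permutations(n, B, strata = strata, seed = seed)
  idx <- perms$idx
  stats <- vapply(seq_len(nrow(idx)), function(b) {
    p <- idx[b, ]
    sum(Kc * L[p, p])
  }, numeric(1)) / n^2
  tol <- 1e-12 * max(1, abs(obs))
  hits <- sum(stats >= obs - tol)
  p <- if (perms$exact) hits / nrow(idx) else (1 + hits) / (nrow(idx) + 1)
  list(statistic = obs,
       # a kernel that is constant after centering (e.g. constant predictor)
       # has no defined effect size but still a valid (trivial) p-value
       dcor = tryCatch(kdc_dcor(K, L), error = function(e) NA_real_),
       p.value = p,
       n_perm = nrow(idx),
       exact = perms$exact,
       perm_stats = stats,
       seed = seed)
}
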