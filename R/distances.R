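#' Pairwise Aitchison distances between compositions
#'
#' The Aitchison distance between two compositions is the Euclidean distance
#' between their clr coordinates; equivalently a scaled double sum over all
#' pairwise log-ratio differences. It is invariant to per-row rescaling and
#' to a joint permutation of the components, and is subcompositionally
#' dominant (dropping a component can only shrink it).
#'
#' @param P Strictly positive matrix, samples in rows (rows need not be
#'   closed; ratios cancel scale).
#' @return An n x n symmetric matrix with zero diagonal and attribute
#'   `metric = "aitchison"`.
#' @export
aitchison_dist <- function(P) {
  D <- as.matrix(stats::dist(clr(P)))
  attr(D, "metric") <- "aitchison"
  D
}

#' Weighted Aitchison distance
#'
#' Generalizes [aitchison_dist()] with positive per-component weights `w`:
#' the log coordinates are centered at the weighted geometric mean
#' `g_w(P) = exp(sum(w_k log P_k) / sum(w))` and each squared coordinate
#' difference is multiplied by `w_r`. Unit weights recover the ordinary
#' Aitchison distance exactly; rescaling all weights by `c` scales squared
#' distances by `c`.
#'
#' @param P Strictly positive matrix, samples in rows.
#' @param w Strictly positive weights, one per component.
#' @return An n x n distance matrix, attribute `metric = "weighted_aitchison"`.
#' @export
weighted_aitchison_dist <- function(P, w) {
  P <- as.matrix(P)
  if (any(!is.finite(P)) || any(P <= 0))
    stop("weighted Aitchison distance requires strictly positive entries")
  w <- as.numeric(w)
  if (length(w) != ncol(P)) stop("need one weight per component")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be strictly positive")
  lg <- log(P)
  wm <- drop(lg %*% w) / sum(w)
  U <- sweep(lg - wm, 2L, sqrt(w), `*`)
  D <- as.matrix(stats::dist(U))
  attr(D, "metric") <- "weighted_aitchison"
  D
}

#' Bray-Curtis dissimilarity
#'
#' `sum_k |P_ik - P_jk| / sum_k (P_ik + P_jk)`. Tolerates zeros, hence the
#' zero-tolerant option for abundance tables that cannot be log-transformed.
#' Entries lie in \[0, 1\] for compositions.
#'
#' @param M Nonnegative matrix with positive row sums.
#' @return An n x n dissimilarity matrix, attribute `metric = "bray_curtis"`.
#' @export
bray_curtis_dist <- function(M) {
  M <- as.matrix(M)
  if (any(!is.finite(M)) || any(M < 0))
    stop("Bray-Curtis requires nonnegative entries")
  rs <- rowSums(M)
  if (any(rs <= 0)) stop("rows with zero total abundance")
  num <- as.matrix(stats::dist(M, method = "manhattan"))
  D <- num / outer(rs, rs, `+`)
  diag(D) <- 0
  attr(D, "metric") <- "bray_curtis"
  D
}

#' Pairwise Euclidean distances
#'
#' Plain L2 distances between rows; provided as the naive comparator that
#' ignores the simplex geometry.
#'
#' @param M Numeric matrix.
#' @return An n x n distance matrix, attribute `metric = "euclidean"`.
#' @export
euclidean_dist <- function(M) {
  D <- as.matrix(stats::dist(as.matrix(M)))
  attr(D, "metric") <- "euclidean"
  D
}
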