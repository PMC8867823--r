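# Kernel (similarity) matrices for the composition side and the predictor
# side of the kernel distance covariance statistic.

# Double centering: H M H with H = I - 11'/n.
double_center <- function(M) {
  M - rowMeans(M) - rep(colMeans(M), each = nrow(M)) + mean(M)
}

#' Distance-induced kernel by double centering
#'
#' Builds the similarity matrix `-1/2 H D* H`, where `H = I - 11'/n` is the
#' centering matrix and `D*` is the matrix of squared distances
#' (`squared = TRUE`, the default used for the composition kernel) or of the
#' distances themselves (`squared = FALSE`, the L2-distance kernel under
#' which the normalized statistic coincides with the squared distance
#' correlation of Szekely et al.). For squared Euclidean distances of points
#' X this is the doubly centered Gram matrix `H X X' H`; row sums are zero.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param squared Use elementwise squared distances (default TRUE).
#' @return A symmetric kernel matrix with attribute
#'   `kernel = "distance_induced"`.
#' @export
dist_kernel <- function(D, squared = TRUE) {
  D <- as.matrix(D)
  check_distance(D)
  S <- if (squared) D^2 else D
  K <- -0.5 * double_center(S)
  K <- (K + t(K)) / 2
  attr(K, "kernel") <- "distance_induced"
  attr(K, "squared") <- squared
  K
}

#' Gaussian (exponential) kernel from a distance matrix
#'
#' `k_ij = exp(-d_ij / gamma)`. The bandwidth `gamma` defaults to the median
#' of the strictly-upper-triangle distances (linear-interpolation median),
#' the customary choice for the Aitchison-distance composition kernel.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param gamma Positive bandwidth, or `"median"`.
#' @return A kernel matrix with unit diagonal, entries in (0, 1], and
#'   attributes `kernel = "gaussian"` and `gamma` (the resolved bandwidth).
#' @export
gaussian_kernel <- function(D, gamma = "median") {
  D <- as.matrix(D)
  check_distance(D)
  g <- resolve_gamma(D, gamma)
  K <- exp(-D / g)
  attr(K, "kernel") <- "gaussian"
  attr(K, "gamma") <- g
  K
}

resolve_gamma <- function(D, gamma) {
  if (identical(gamma, "median")) {
    g <- stats::median(D[upper.tri(D)])
    if (!is.finite(g) || g <= 0)
      stop("degenerate bandwidth: all pairwise distances are zero")
    g
  } else {
    if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
      stop("'gamma' must be a positive number or \"median\"")
    as.numeric(gamma)
  }
}

check_distance <- function(D, tol = 1e-10) {
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > tol) stop("distance matrix must be symmetric")
  if (any(D < -tol)) stop("distance matrix must be nonnegative")
  invisible(D)
}

#' Predictor-side kernel
#'
#' Binary predictors use the Hamming-distance kernel
#' `l_ij = exp(-|x_i - x_j|)` on a 0/1 coding (arbitrary two-level labels
#' are recoded automatically); continuous predictors use the linear kernel
#' `l_ij = x_i x_j` after mean-centering and (by default) unit-scaling,
#' which stabilizes the scale-sensitive linear kernel without changing the
#' centered statistic.
#'
#' @param x Predictor vector (numeric, factor or character).
#' @param kind `"auto"` (two unique values -> binary), `"binary"` or
#'   `"continuous"`.
#' @param scale For continuous predictors, divide by the standard deviation.
#' @return An n x n kernel matrix with attribute `kind`.
#' @export
predictor_kernel <- function(x, kind = c("auto", "binary", "continuous"),
                             scale = TRUE) {
  kind <- match.arg(kind)
  ux <- unique(x)
  if (kind == "auto") kind <- if (length(ux) <= 2L) "binary" else "continuous"
  if (kind == "binary") {
    if (length(ux) > 2L)
      stop("predictor has more than 2 levels; one-hot encode it as ",
           "covariates or use stratification")
    xb <- as.numeric(factor(x)) - 1
    L <- exp(-abs(outer(xb, xb, `-`)))
  } else {
    x <- as.numeric(x)
    if (any(!is.finite(x))) stop("continuous predictor must be finite")
    xc <- x - mean(x)
    if (scale) {
      s <- stats::sd(xc)
      if (s > 0) xc <- xc / s
    }
    L <- outer(xc, xc)
  }
  attr(L, "kind") <- kind
  L
}

#' Stratified kernel for categorical-covariate adjustment
#'
#' Zeroes every similarity between samples belonging to different strata,
#' leaving within-stratum entries of the (exponential-form) kernel
#' untouched. Sorting samples by stratum exposes the block structure. The
#' stratified kernel of a strictly positive definite within-stratum kernel
#' is itself strictly positive definite.
#'
#' @param K Kernel matrix (built from a distance via [gaussian_kernel()] or
#'   [predictor_kernel()]).
#' @param strata Vector of n categorical labels. Singleton strata trigger a
#'   warning: they contribute no between-sample information.
#' @return The masked kernel matrix, attribute `stratified = TRUE`.
#' @export
stratify_kernel <- function(K, strata) {
  K <- as.matrix(K)
  strata <- as.factor(strata)
  if (length(strata) != nrow(K)) stop("'strata' must have one label per sample")
  sizes <- table(strata)
  if (any(sizes == 1L))
    warning("stratum/strata of size 1: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "),
            " contribute no between-sample information")
  mask <- outer(strata, strata, `==`)
  out <- K * mask
  attr(out, "kernel") <- attr(K, "kernel")
  attr(out, "gamma") <- attr(K, "gamma")
  attr(out, "stratified") <- TRUE
  out
}

#' Clip negative eigenvalues to restore positive semidefiniteness
#'
#' Symmetrizes `K`, and if its smallest eigenvalue falls below
#' `-tol * lambda_max` replaces all negative eigenvalues by zero and
#' reconstructs (the Frobenius-nearest PSD matrix among spectral
#' truncations). Smaller negativity is treated as round-off and left alone.
#' Needed for the Bray-Curtis kernel, which is not guaranteed PSD.
#'
#' @param K Symmetric matrix.
#' @param tol Relative clipping threshold (default 1e-10).
#' @return `K`, possibly reconstructed, with attribute `psd_clipped`
#'   indicating whether clipping occurred.
#' @export
psd_clip <- function(K, tol = 1e-10) {
  K <- (as.matrix(K) + t(as.matrix(K))) / 2
  e <- eigen(K, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (min(e$values) >= -tol * max(lmax, .Machine$double.eps)) {
    attr(K, "psd_clipped") <- FALSE
    return(K)
  }
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(K)
  attr(out, "psd_clipped") <- TRUE
  out
}
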