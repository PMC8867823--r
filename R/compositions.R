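#' Closure operation: rescale nonnegative parts to unit sum
#'
#' Divides every component of a vector (or every row of a matrix) by its sum,
#' projecting nonnegative abundance data onto the simplex. This is the
#' standard closure operator of compositional data analysis.
#'
#' @param x A nonnegative numeric vector, or a matrix whose rows are
#'   rescaled independently.
#' @return An object of the same shape as `x` with unit (row) sums.
#' @examples
#' closure(c(2, 2, 4))
#' @export
closure <- function(x) {
  if (is.null(dim(x))) {
    if (!is.numeric(x) || any(!is.finite(x))) stop("'x' must be finite numeric")
    if (any(x < 0)) stop("closure requires nonnegative entries")
    s <- sum(x)
    if (s <= 0) stop("closure of an all-zero vector is undefined")
    return(x / s)
  }
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) stop("'x' must be finite numeric")
  if (any(x < 0)) stop("closure requires nonnegative entries")
  rs <- rowSums(x)
  if (any(rs <= 0)) {
    stop("closure undefined for all-zero row(s): ",
         paste(which(rs <= 0), collapse = ", "))
  }
  x / rs
}

#' Validate and normalize a composition matrix
#'
#' Coerces an n x q table of proportions to a strictly positive matrix with
#' rows summing to one. Rows whose sums deviate from 1 by no more than `tol`
#' (rounded input files are common) are re-closed; larger deviations are an
#' error. Zeros are refused: zero handling belongs on the count scale (see
#' [counts_to_composition()]) or to the zero-tolerant Bray-Curtis kernel.
#'
#' @param x Numeric matrix or data frame of proportions, samples in rows.
#' @param tol Row-sum acceptance tolerance before re-closure.
#' @return A strictly positive numeric matrix with unit row sums.
#' @export
as_composition <- function(x, tol = 0.01) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("a composition matrix needs at least 2 samples and 2 components")
  if (any(!is.finite(x))) stop("non-finite entries in composition matrix")
  if (any(x < 0)) stop("negative entries in composition matrix")
  if (any(x == 0)) {
    bad <- which(x == 0, arr.ind = TRUE)
    stop("zero proportions found (e.g. sample ", bad[1, 1], ", component ",
         bad[1, 2], "); supply counts with a pseudocount ",
         "(counts_to_composition) or use the Bray-Curtis kernel")
  }
  rs <- rowSums(x)
  off <- abs(rs - 1) > tol
  if (any(off)) {
    stop("row(s) ", paste(utils::head(which(off), 5L), collapse = ", "),
         " do not sum to 1 within tolerance ", tol)
  }
  x / rs
}

#' Convert a count matrix to a composition with pseudocount zero handling
#'
#' Rows of cell-type counts are closed to proportions. If any zero count is
#' present anywhere in the matrix, `pseudocount` is first added to every cell
#' of the matrix (a global shift keeps samples comparable and preserves the
#' ordering between zero and near-zero counts) before closure.
#'
#' @param counts Nonnegative integer matrix, samples in rows; every row must
#'   contain at least one cell.
#' @param pseudocount Nonnegative number added to all counts when zeros are
#'   present (default 1). With zeros present and `pseudocount = 0` an error
#'   identifies the offending cells.
#' @return A strictly positive composition matrix (unit row sums).
#' @export
counts_to_composition <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0) || !is_whole(counts))
    stop("'counts' must be a matrix of nonnegative integers")
  if (any(rowSums(counts) <= 0))
    stop("row(s) with zero total count: ",
         paste(which(rowSums(counts) <= 0), collapse = ", "))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("'pseudocount' must be a single nonnegative number")
  if (any(counts == 0)) {
    if (pseudocount == 0) {
      bad <- which(counts == 0, arr.ind = TRUE)
      lab <- apply(utils::head(bad, 5L), 1L, function(z)
        paste0("(sample ", z[1], ", component ", z[2], ")"))
      stop("zero counts at ", paste(lab, collapse = ", "),
           if (nrow(bad) > 5L) ", ..." else "",
           "; a positive pseudocount is required")
    }
    counts <- counts + pseudocount
  }
  as_composition(closure(counts), tol = 1e-6)
}

#' Additive log-ratio (alr) transform
#'
#' Maps each composition row to the q-1 log ratios against a reference
#' component, `ln(P_k / P_ref)`. The reference defaults to the last column.
#' Ratios cancel any per-row scaling, so strictly positive rows need not be
#' closed beforehand.
#'
#' @param P Strictly positive matrix, samples in rows.
#' @param ref Reference component: column index or name (default last).
#' @return An n x (q-1) matrix with attributes `transform = "alr"` and `ref`
#'   (the reference column index in the original matrix).
#' @seealso [alr_inv()], [clr()]
#' @export
alr <- function(P, ref = ncol(P)) {
  P <- as.matrix(P)
  if (any(!is.finite(P)) || any(P <= 0))
    stop("alr requires strictly positive entries")
  if (is.character(ref)) {
    ref <- match(ref, colnames(P))
    if (is.na(ref)) stop("unknown reference component")
  }
  ref <- as.integer(ref)
  if (ref < 1L || ref > ncol(P)) stop("'ref' out of range")
  lg <- log(P)
  Y <- lg[, -ref, drop = FALSE] - lg[, ref]
  attr(Y, "transform") <- "alr"
  attr(Y, "ref") <- ref
  attr(Y, "ref_name") <- colnames(P)[ref]
  Y
}

#' Inverse additive log-ratio transform
#'
#' Reconstructs compositions from alr coordinates: the reference component is
#' appended as a zero log-coordinate, rows are exponentiated (after
#' subtracting the row maximum, so large coordinates cannot overflow) and
#' closed. `alr_inv(alr(P))` reproduces `P` exactly up to round-off.
#'
#' @param Y Matrix of alr coordinates; the `ref` attribute set by [alr()] (or
#'   a `ref` argument) records where the reference column is re-inserted.
#' @param ref Original column index of the reference component; defaults to
#'   the attribute stored by [alr()], else last position.
#' @return A composition matrix with q = ncol(Y) + 1 columns.
#' @export
alr_inv <- function(Y, ref = NULL) {
  Y <- as.matrix(Y)
  ref <- ref %||% attr(Y, "ref") %||% (ncol(Y) + 1L)
  ref <- as.integer(ref)
  q <- ncol(Y) + 1L
  if (ref < 1L || ref > q) stop("'ref' out of range")
  full <- matrix(0, nrow(Y), q)
  full[, -ref] <- Y
  m <- apply(full, 1L, max)
  P <- exp(full - m)
  cn <- colnames(Y)
  if (!is.null(cn)) {
    nm <- character(q)
    nm[-ref] <- cn
    nm[ref] <- attr(Y, "ref_name") %||% "ref"
    colnames(P) <- nm
  }
  rownames(P) <- rownames(Y)
  closure(P)
}

#' Centered log-ratio (clr) transform
#'
#' Maps each row to `ln(P_k / g(P))` where `g` is the row geometric mean.
#' clr rows sum to zero; the Euclidean distance between clr rows is the
#' Aitchison distance.
#'
#' @param P Strictly positive matrix, samples in rows.
#' @return An n x q matrix with zero row sums and attribute
#'   `transform = "clr"`.
#' @export
clr <- function(P) {
  P <- as.matrix(P)
  if (any(!is.finite(P)) || any(P <= 0))
    stop("clr requires strictly positive entries")
  lg <- log(P)
  Y <- lg - rowMeans(lg)
  attr(Y, "transform") <- "clr"
  Y
}

#' Inverse centered log-ratio transform
#'
#' @param Y Matrix of clr coordinates.
#' @return The composition matrix `closure(exp(Y))`, computed with the same
#'   overflow guard as [alr_inv()].
#' @export
clr_inv <- function(Y) {
  Y <- as.matrix(Y)
  m <- apply(Y, 1L, max)
  P <- exp(Y - m)
  dimnames(P) <- dimnames(Y)
  closure(P)
}

# clr of a single probability vector (used for true-effect summaries)
clr_vec <- function(p) {
  lp <- log(p)
  lp - mean(lp)
}
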