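# Covariate adjustment: linear residualization on log-ratio coordinates.

# Build a full-rank design matrix (intercept + dummy-coded categorical
# levels) from a covariate specification: vector, matrix or data frame.
covariate_design <- function(Z) {
  if (is.null(Z)) stop("no covariates supplied")
  df <- if (is.data.frame(Z)) Z else as.data.frame(Z)
  df[] <- lapply(df, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  })
  constant <- vapply(df, function(col) length(unique(col)) < 2L, logical(1))
  df <- df[!constant]             # a constant covariate is just the intercept
  X <- if (ncol(df) == 0L)
    matrix(1, nrow(as.data.frame(Z)), 1L,
           dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("covariate design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  X
}

#' Residualize a matrix on covariates
#'
#' Returns `(I - H_Z) M`, the residuals of every column of `M` from a linear
#' regression on the covariate design (intercept plus dummy-coded
#' categorical levels). Residual columns are orthogonal to every design
#' column; the projection is idempotent.
#'
#' @param M Numeric matrix or vector (n rows).
#' @param Z Covariates: vector, matrix or data frame with n rows. A
#'   rank-deficient design is an error naming the collinear columns.
#' @return The residual matrix (or vector when `M` is a vector).
#' @export
residualize <- function(M, Z) {
  vec <- is.null(dim(M))
  M <- as.matrix(M)
  X <- covariate_design(Z)
  if (nrow(X) != nrow(M)) stop("covariates and data have different row counts")
  R <- qr.resid(qr(X), M)
  if (vec) drop(R) else R
}

#' Covariate-adjust a composition through log-ratio residualization
#'
#' Transforms the composition to log-ratio coordinates, removes the linear
#' effect of the covariates by projection, and maps the residuals back to
#' the simplex. The alr and clr routes give compositions with identical
#' Aitchison geometry (the clr coordinates differ only by a row constant,
#' which log-ratios ignore), so the choice is immaterial downstream.
#'
#' @param P Composition matrix (strictly positive rows).
#' @param Z Covariates (vector, matrix or data frame).
#' @param transform `"alr"` (default) or `"clr"`.
#' @param ref Reference component for the alr route (default last column).
#' @return The adjusted composition matrix.
#' @export
adjust_composition <- function(P, Z, transform = c("alr", "clr"),
                               ref = ncol(P)) {
  transform <- match.arg(transform)
  P <- as.matrix(P)
  if (transform == "alr") {
    Y <- alr(P, ref = ref)
    Yz <- residualize(Y, Z)
    attr(Yz, "ref") <- attr(Y, "ref")
    attr(Yz, "ref_name") <- attr(Y, "ref_name")
    alr_inv(Yz)
  } else {
    clr_inv(residualize(clr(P), Z))
  }
}
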