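#' Kernel distance covariance test for compositional abundance data
#'
#' `codak()` tests whether an n x q compositional profile (cell-type
#' proportions or counts, samples in rows) is associated with a predictor,
#' optionally adjusting for covariates. A kernel is built on the
#' compositions (by default a Gaussian kernel on Aitchison distances with
#' median bandwidth), a second kernel on the predictor (Hamming for binary,
#' linear for continuous), and the association is measured by the kernel
#' distance covariance `trace(K H L H) / n^2`, with significance from a
#' permutation test and the distance correlation as effect size.
#'
#' Covariate handling: with `covariates`, the composition is mapped to alr
#' coordinates, residualized on the covariate design, mapped back, and the
#' predictor is residualized likewise; permutations follow either the
#' Freedman-Lane scheme (reduced-model residuals are permuted and
#' re-residualized before each permuted statistic; better type-I error
#' control, the default) or the Kennedy-Cade scheme (both sides residualized
#' once, then plain permutation; slightly more powerful but can be
#' anticonservative). With `strata` (a categorical covariate), similarities
#' between samples in different strata are zeroed in both kernels and
#' permutations are restricted within strata.
#'
#' @param object Composition matrix (proportions or integer counts, samples
#'   in rows), or a formula `P ~ x + z1 + ...` whose left side evaluates to
#'   that matrix, first right-hand term is the predictor and any further
#'   terms are covariates.
#' @param predictor Predictor vector (binary labels or numeric).
#' @param covariates Optional covariates (vector, matrix or data frame) for
#'   alr-residualization adjustment.
#' @param strata Optional categorical labels for stratified-kernel
#'   adjustment (mutually exclusive with `covariates`). A data frame with
#'   several categorical columns is crossed into a single stratum label with
#'   a warning, since small strata cost power.
#' @param kernel Composition kernel: `"ad_gaussian"` (Gaussian on Aitchison
#'   distance, median bandwidth; default), `"ad_linear"` (distance-induced,
#'   double-centered squared Aitchison distance), `"bc"` (distance-induced
#'   Bray-Curtis, eigenvalue-clipped to PSD; tolerates zeros) or
#'   `"euclidean"` (Gaussian on Euclidean distance, for comparison only).
#' @param scheme Permutation scheme used when `covariates` are supplied:
#'   `"freedman_lane"` (default) or `"kennedy_cade"`. The observed statistic
#'   is identical under both.
#' @param predictor_kind `"auto"` (default: two unique values -> binary),
#'   `"binary"` or `"continuous"`.
#' @param gamma Bandwidth for Gaussian-type kernels: positive number or
#'   `"median"`. For the stratified path the bandwidth is resolved from the
#'   unstratified distance matrix, so within-stratum similarities equal the
#'   unadjusted kernel's entries.
#' @param n_perm Number of permutations (default 10000). All permutations
#'   are enumerated instead when `n! <= 10000` and no strata are involved.
#' @param seed Optional integer seed for the permutation draw.
#' @param pseudocount Added to all counts before closure when the count
#'   matrix contains zeros (default 1); ignored for proportion input.
#' @param alr_ref Reference component for the alr adjustment route (index or
#'   name; default last column).
#' @param ... Passed between methods.
#' @return An object of class `"codak"`: a list with elements `statistic`
#'   (the KDC statistic), `dcor` (effect size in \[0, 1\]), `p.value`,
#'   `n_perm`, `exact`, `perm_stats`, `kernel`, `gamma`, `predictor_kind`,
#'   `adjustment`, `n`, `q`, `seed` and `call`. Methods: `print`, `summary`,
#'   `plot`.
#' @examples
#' set.seed(1)
#' counts <- matrix(rpois(8 * 5, lambda = 200), 8, 5)
#' group <- rep(c("A", "B"), each = 4)
#' codak(counts, group, n_perm = 500, seed = 42)
#' @export
codak <- function(object, ...) UseMethod("codak")

#' @rdname codak
#' @export
codak.default <- function(object, predictor, covariates = NULL, strata = NULL,
                          kernel = c("ad_gaussian", "ad_linear", "bc",
                                     "euclidean"),
                          scheme = c("freedman_lane", "kennedy_cade"),
                          predictor_kind = c("auto", "binary", "continuous"),
                          gamma = "median", n_perm = 10000, seed = NULL,
                          pseudocount = 1, alr_ref = NULL, ...) {
  kernel <- match.arg(kernel)
  scheme <- match.arg(scheme)
  predictor_kind <- match.arg(predictor_kind)
  if (!is.null(covariates) && !is.null(strata))
    stop("use either 'covariates' (alr adjustment) or 'strata' ",
         "(stratified kernel), not both")

  P <- prepare_composition(object, kernel = kernel, pseudocount = pseudocount)
  n <- nrow(P)
  if (length(predictor) != n)
    stop("'predictor' must have one value per sample")

  adjustment <- if (!is.null(strata)) "stratified"
    else if (!is.null(covariates)) paste0("alr_", if (scheme == "kennedy_cade")
      "kc" else "fl")
    else "none"

  fit <- switch(adjustment,
    none = codak_fit_plain(P, predictor, kernel, predictor_kind, gamma,
                           n_perm, seed),
    alr_kc = ,
    alr_fl = codak_fit_alr(P, predictor, covariates, scheme, kernel,
                           predictor_kind, gamma, n_perm, seed,
                           alr_ref %||% ncol(P)),
    stratified = codak_fit_sk(P, predictor, strata, kernel, predictor_kind,
                              gamma, n_perm, seed))

  structure(c(fit, list(adjustment = adjustment, n = n, q = ncol(P),
                        component_ids = colnames(P), seed = seed,
                        call = match.call())),
            class = "codak")
}

#' @rdname codak
#' @param data Environment or data frame in which the formula terms are
#'   evaluated.
#' @export
codak.formula <- function(object, data = NULL, strata = NULL, ...) {
  env <- environment(object)
  if (length(object) != 3L)
    stop("formula must have the form composition ~ predictor + covariates")
  comp <- eval(object[[2L]], data, env)
  tt <- stats::terms(object)
  labs <- attr(tt, "term.labels")
  if (length(labs) < 1L) stop("formula needs a predictor term")
  predictor <- eval(str2lang(labs[1L]), data, env)
  covariates <- NULL
  if (length(labs) > 1L) {
    covariates <- as.data.frame(
      lapply(stats::setNames(labs[-1L], labs[-1L]),
             function(l) eval(str2lang(l), data, env)))
  }
  strata <- eval(substitute(strata), data, parent.frame())
  res <- codak.default(comp, predictor, covariates = covariates,
                       strata = strata, ...)
  res$call <- match.call()
  res
}

# ---- internal fitting paths -------------------------------------------------

prepare_composition <- function(object, kernel, pseudocount) {
  M <- as.matrix(object)
  storage.mode(M) <- "double"
  if (is.null(colnames(M))) colnames(M) <- paste0("C", seq_len(ncol(M)))
  counts <- is_whole(M) && max(M) > 1 + 1e-8
  if (counts) {
    if (kernel == "bc") return(closure(M))
    return(counts_to_composition(M, pseudocount = pseudocount))
  }
  if (kernel == "bc") {
    if (any(M < 0)) stop("negative entries in abundance matrix")
    if (any(rowSums(M) <= 0)) stop("rows with zero total abundance")
    return(closure(M))
  }
  as_composition(M)
}

comp_dist <- function(P, kernel) {
  switch(kernel,
         ad_gaussian = ,
         ad_linear = aitchison_dist(P),
         bc = bray_curtis_dist(P),
         euclidean = euclidean_dist(P))
}

comp_kernel <- function(D, kernel, gamma) {
  switch(kernel,
         ad_gaussian = ,
         euclidean = gaussian_kernel(D, gamma),
         ad_linear = dist_kernel(D, squared = TRUE),
         bc = psd_clip(dist_kernel(D, squared = TRUE)))
}

kernel_label <- function(kernel) {
  switch(kernel,
         ad_gaussian = "gaussian (Aitchison distance)",
         ad_linear = "distance-induced (squared Aitchison distance)",
         bc = "distance-induced (Bray-Curtis, PSD-clipped)",
         euclidean = "gaussian (Euclidean distance)")
}

codak_fit_plain <- function(P, x, kernel, predictor_kind, gamma, n_perm,
                            seed) {
  D <- comp_dist(P, kernel)
  K <- comp_kernel(D, kernel, gamma)
  L <- predictor_kernel(x, kind = predictor_kind)
  res <- kdc_perm_test(K, L, B = n_perm, seed = seed)
  c(res[c("statistic", "dcor", "p.value", "n_perm", "exact", "perm_stats")],
    list(kernel = kernel, gamma = attr(K, "gamma") %||% NA_real_,
         predictor_kind = attr(L, "kind")))
}

codak_fit_alr <- function(P, x, Z, scheme, kernel, predictor_kind, gamma,
                          n_perm, seed, alr_ref) {
  kind <- attr(predictor_kernel(x, kind = predictor_kind), "kind")
  xn <- if (kind == "binary") as.numeric(factor(x)) - 1 else as.numeric(x)
  X <- covariate_design(Z)
  qrX <- qr(X)
  Y <- alr(P, ref = alr_ref)
  E <- qr.resid(qrX, Y)
  attr(E, "ref") <- attr(Y, "ref")
  attr(E, "ref_name") <- attr(Y, "ref_name")
  Pz <- alr_inv(E)
  xz <- drop(qr.resid(qrX, xn))
  K <- comp_kernel(comp_dist(Pz, kernel), kernel, gamma)
  L <- predictor_kernel(xz, kind = "continuous")
  if (scheme == "kennedy_cade") {
    res <- kdc_perm_test(K, L, B = n_perm, seed = seed)
    stats <- res$perm_stats
    out <- res
  } else {
    # Freedman-Lane: permute the reduced-model residuals, re-residualize,
    # rebuild the composition kernel, and compare against the fixed
    # residualized predictor kernel.
    n <- nrow(P)
    Lc <- double_center(L)
    obs <- sum(K * Lc) / n^2
    perms <- draw_permutations(n, n_perm, seed = seed)
    idx <- perms$idx
    ref <- attr(Y, "ref")
    stats <- vapply(seq_len(nrow(idx)), function(b) {
      Eb <- qr.resid(qrX, E[idx[b, ], , drop = FALSE])
      attr(Eb, "ref") <- ref
      Kb <- comp_kernel(comp_dist(alr_inv(Eb), kernel), kernel, gamma)
      sum(Kb * Lc)
    }, numeric(1)) / n^2
    tol <- 1e-12 * max(1, abs(obs))
    hits <- sum(stats >= obs - tol)
    p <- if (perms$exact) hits / nrow(idx) else (1 + hits) / (nrow(idx) + 1)
    out <- list(statistic = obs, dcor = kdc_dcor(K, L), p.value = p,
                n_perm = nrow(idx), exact = perms$exact, perm_stats = stats)
  }
  c(out[c("statistic", "dcor", "p.value", "n_perm", "exact", "perm_stats")],
    list(kernel = kernel, gamma = attr(K, "gamma") %||% NA_real_,
         predictor_kind = kind))
}

codak_fit_sk <- function(P, x, strata, kernel, predictor_kind, gamma, n_perm,
                         seed) {
  if (kernel == "ad_linear")
    stop("the stratified kernel is defined on the exponential (gaussian) ",
         "form; use kernel = \"ad_gaussian\"")
  if (!is.null(dim(strata)) && ncol(as.data.frame(strata)) > 1L) {
    warning("multiple categorical covariates crossed into a single stratum ",
            "label; small strata reduce the effective sample size")
    strata <- interaction(as.data.frame(strata), drop = TRUE)
  }
  strata <- as.factor(strata)
  if (length(strata) != nrow(P)) stop("'strata' must have one label per sample")
  D <- comp_dist(P, kernel)
  g <- resolve_gamma(D, gamma)   # unstratified median: Eq-form masked kernel
  K <- stratify_kernel(gaussian_kernel(D, g), strata)
  L <- stratify_kernel(predictor_kernel(x, kind = predictor_kind), strata)
  res <- kdc_perm_test(K, L, B = n_perm, seed = seed, strata = strata)
  c(res[c("statistic", "dcor", "p.value", "n_perm", "exact", "perm_stats")],
    list(kernel = kernel, gamma = g, predictor_kind = attr(L, "kind")))
}

# ---- spec-surface wrappers --------------------------------------------------

#' Unadjusted CODAK association test
#'
#' Thin wrapper around [codak()] without covariates.
#' @inheritParams codak.default
#' @param P Composition or count matrix, samples in rows.
#' @param x Predictor vector.
#' @param ... Passed to [codak.default()].
#' @return A `"codak"` object.
#' @export
codak_test <- function(P, x, ...) {
  res <- codak.default(P, x, ...)
  res$call <- match.call()
  res
}

#' CODAK with alr-residualization covariate adjustment
#'
#' @inheritParams codak_test
#' @param covariates Covariates (vector, matrix or data frame).
#' @param scheme `"freedman_lane"` (default) or `"kennedy_cade"`.
#' @return A `"codak"` object.
#' @export
codak_alr <- function(P, x, covariates,
                      scheme = c("freedman_lane", "kennedy_cade"), ...) {
  res <- codak.default(P, x, covariates = covariates,
                       scheme = match.arg(scheme), ...)
  res$call <- match.call()
  res
}

#' CODAK with stratified-kernel covariate adjustment
#'
#' @inheritParams codak_test
#' @param strata Categorical covariate labels defining the strata.
#' @return A `"codak"` object.
#' @export
codak_sk <- function(P, x, strata, ...) {
  res <- codak.default(P, x, strata = strata, ...)
  res$call <- match.call()
  res
}

# ---- methods ----------------------------------------------------------------

#' @export
print.codak <- function(x, digits = 4, ...) {
  cat("\n\tKernel distance covariance test of compositional association\n\n")
  cat("samples:", x$n, "  components:", x$q, "\n")
  cat("composition kernel:", kernel_label(x$kernel),
      if (is.finite(x$gamma)) paste0("[gamma = ", signif(x$gamma, digits), "]")
      else "", "\n")
  cat("predictor kernel:  ",
      if (x$predictor_kind == "binary") "Hamming (binary)"
      else "linear (continuous, centered)", "\n")
  cat("adjustment:        ",
      switch(x$adjustment,
             none = "none",
             alr_kc = "alr residualization (Kennedy-Cade permutations)",
             alr_fl = "alr residualization (Freedman-Lane permutations)",
             stratified = "stratified kernel (within-strata permutations)"),
      "\n\n")
  cat("KDC statistic =", format(x$statistic, digits = digits),
      "  dcor =", format(x$dcor, digits = digits), "\n")
  cat("permutation p-value =", format.pval(x$p.value, digits = digits),
      paste0("(", x$n_perm,
             if (x$exact) " enumerated permutations, exact)"
             else " sampled permutations)"), "\n\n")
  invisible(x)
}

#' @export
summary.codak <- function(object, ...) {
  structure(list(fit = object,
                 null_quantiles = stats::quantile(
                   object$perm_stats, c(0.5, 0.9, 0.95, 0.99))),
            class = "summary.codak")
}

#' @export
print.summary.codak <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("permutation null quantiles of the KDC statistic:\n")
  print(signif(x$null_quantiles, digits))
  cat("\ndcor is the distance correlation between the compositional profile",
      "\nand the predictor: 0 = no detected association, 1 = perfect.\n")
  invisible(x)
}

#' Plot the permutation null distribution of a CODAK test
#'
#' Histogram of the permuted KDC statistics with the observed statistic
#' marked.
#'
#' @param x A `"codak"` object.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.codak <- function(x, ...) {
  graphics::hist(x$perm_stats, breaks = 40, col = "grey85", border = "white",
                 main = "Permutation null of the KDC statistic",
                 xlab = "KDC statistic", ...)
  graphics::abline(v = x$statistic, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = sprintf("observed (p = %s)",
                                                format.pval(x$p.value)),
                   col = "firebrick", lwd = 2, bty = "n")
  invisible(x)
}
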