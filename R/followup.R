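# Follow-up ranking of individual components after a detected association:
# leave-one-out dcor, optimized weighted Aitchison distance, and a log
# odds-ratio baseline.

new_ranking <- function(components, scores, method, extra = list()) {
  ord <- order(-scores)                 # stable: ties keep component order
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  tied <- duplicated(scores) | duplicated(scores, fromLast = TRUE)
  out <- data.frame(component = components, score = scores, rank = ranks,
                    tied = tied, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("codak_ranking", "data.frame"), method = method,
            details = extra)
}

#' @export
print.codak_ranking <- function(x, digits = 4, ...) {
  cat("Component ranking (method: ", attr(x, "method"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$score <- signif(df$score, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Drop one component and re-close
#'
#' Removes a single column from a composition and re-closes the rows,
#' producing the subcomposition used by the leave-one-out statistic. By
#' subcompositional dominance the Aitchison distance between any two rows
#' can only shrink.
#'
#' @param P Composition matrix with at least 3 components.
#' @param comp Column index or name to drop.
#' @return The re-closed n x (q-1) composition.
#' @export
drop_component <- function(P, comp) {
  P <- as.matrix(P)
  if (ncol(P) < 3L)
    stop("dropping a component needs at least 3 components")
  if (is.character(comp)) {
    comp <- match(comp, colnames(P))
    if (is.na(comp)) stop("unknown component")
  }
  comp <- as.integer(comp)
  if (comp < 1L || comp > ncol(P)) stop("unknown component")
  closure(P[, -comp, drop = FALSE])
}

# Scalar (univariate) distance correlation of Szekely et al., computed from
# doubly centered L2-distance kernels. Returns NA for a constant input.
scalar_dcor <- function(a, b) {
  Da <- abs(outer(a, a, `-`))
  Db <- abs(outer(b, b, `-`))
  if (max(Da) == 0 || max(Db) == 0) return(NA_real_)
  val <- kdc_dcor(dist_kernel(Da, squared = FALSE),
                  dist_kernel(Db, squared = FALSE))
  sqrt(max(0, val))
}

#' Leave-one-out distance correlation ranking
#'
#' For each component `c`, the composition is reduced by [drop_component()]
#' and the distance correlation with the predictor recomputed using the same
#' kernel family (with a freshly resolved median bandwidth: each dcor is a
#' self-contained statistic). The score `max(0, dcor(P, x) - dcor(P_-c, x))`
#' measures how much component `c` contributes to the detected association;
#' components are ranked by descending score, ties broken by column order
#' and flagged.
#'
#' @param P Composition (or count) matrix with at least 3 components.
#' @param x Predictor vector.
#' @param kernel `"ad_gaussian"` (default) or `"ad_linear"`.
#' @param gamma Bandwidth specification, normally `"median"`.
#' @param predictor_kind See [predictor_kernel()].
#' @param pseudocount For count input containing zeros.
#' @return A `"codak_ranking"` data frame (component, score, rank, tied)
#'   with the full-composition dcor in `attr(, "details")`.
#' @export
loo_dcor <- function(P, x, kernel = c("ad_gaussian", "ad_linear"),
                     gamma = "median",
                     predictor_kind = c("auto", "binary", "continuous"),
                     pseudocount = 1) {
  kernel <- match.arg(kernel)
  predictor_kind <- match.arg(predictor_kind)
  if (ncol(as.matrix(P)) < 3L)
    stop("leave-one-out ranking needs at least 3 components")
  P <- prepare_composition(P, kernel = kernel, pseudocount = pseudocount)
  L <- predictor_kernel(x, kind = predictor_kind)
  dc <- function(Q) kdc_dcor(comp_kernel(aitchison_dist(Q), kernel, gamma), L)
  full <- dc(P)
  scores <- vapply(seq_len(ncol(P)), function(cc)
    max(0, full - dc(drop_component(P, cc))), numeric(1))
  new_ranking(colnames(P), scores, "loo",
              extra = list(full_dcor = full, kernel = kernel))
}

#' Weighted distance correlation ranking
#'
#' Per-component association strengths `beta_k` (the univariate distance
#' correlation between component k's proportions and the predictor) are
#' turned into weights `w_k = beta_k^g / sqrt(sum(beta^2g))` for an exponent
#' `g` searched over a logarithmic grid; each weight vector defines a
#' weighted Aitchison distance whose Gaussian kernel yields a weighted
#' distance correlation with the predictor, and the exponent maximizing it
#' is retained. The equal-weight limit (`g -> 0`, identical to the
#' unweighted dcor) is included in the search as `gamma = 0`, so the
#' optimized value is never below the unweighted one on the grid. Because
#' the weights are a monotone power of `beta`, the component ranking equals
#' the `beta` ordering for every positive exponent.
#'
#' @inheritParams loo_dcor
#' @param gamma_grid Positive exponents searched (default `2^(-3..6)`, 10
#'   logarithmically spaced points).
#' @return A list of class `"codak_wdcor"`: `gamma_star` (0 means the
#'   equal-weight limit won), `weights` (unit Euclidean norm),
#'   `weighted_dcor`, `grid_trace` (data frame of exponent vs objective),
#'   `betas`, `uniform_dcor` and `ranking` (a `"codak_ranking"`).
#' @export
weighted_dcor_rank <- function(P, x,
                               gamma_grid = 2^seq(-3, 6, length.out = 10),
                               gamma = "median",
                               predictor_kind = c("auto", "binary",
                                                  "continuous"),
                               pseudocount = 1) {
  predictor_kind <- match.arg(predictor_kind)
  if (any(!is.finite(gamma_grid)) || any(gamma_grid <= 0))
    stop("'gamma_grid' must contain positive exponents")
  gamma_grid <- sort(unique(gamma_grid))
  P <- prepare_composition(P, kernel = "ad_gaussian",
                           pseudocount = pseudocount)
  q <- ncol(P)
  L <- predictor_kernel(x, kind = predictor_kind)
  xn <- if (attr(L, "kind") == "binary") as.numeric(factor(x)) - 1
        else as.numeric(x)
  betas <- vapply(seq_len(q), function(k) scalar_dcor(P[, k], xn), numeric(1))
  if (anyNA(betas)) {
    warning("constant component(s) ",
            paste(colnames(P)[is.na(betas)], collapse = ", "),
            ": beta set to 0")
    betas[is.na(betas)] <- 0
  }
  objective <- function(w)
    kdc_dcor(gaussian_kernel(weighted_aitchison_dist(P, w), gamma), L)
  weights_at <- function(g) {
    if (g == 0) return(rep(1 / sqrt(q), q))
    bg <- betas^g
    nrm <- sqrt(sum(bg^2))
    if (nrm == 0) rep(1 / sqrt(q), q) else bg / nrm
  }
  cand <- c(0, gamma_grid)
  obj <- vapply(cand, function(g) {
    w <- weights_at(g)
    if (any(w <= 0)) w <- pmax(w, 1e-12)  # zero-beta components: inert weight
    objective(w)
  }, numeric(1))
  best <- which.max(obj)
  gamma_star <- cand[best]
  weights <- weights_at(gamma_star)
  # ranks follow the beta ordering (equal to the weight ordering for any
  # positive exponent); use the smallest positive exponent when the
  # equal-weight limit wins so ranks stay informative
  g_rank <- if (gamma_star > 0) gamma_star else gamma_grid[1L]
  ranking <- new_ranking(colnames(P), weights_at(g_rank), "weighted_dcor",
                         extra = list(gamma_star = gamma_star,
                                      betas = betas))
  structure(list(gamma_star = gamma_star, weights = weights,
                 weighted_dcor = obj[best],
                 grid_trace = data.frame(gamma = cand, objective = obj),
                 betas = stats::setNames(betas, colnames(P)),
                 uniform_dcor = obj[1L], ranking = ranking),
            class = "codak_wdcor")
}

#' @export
print.codak_wdcor <- function(x, digits = 4, ...) {
  cat("Weighted distance correlation ranking\n")
  cat("optimal exponent gamma* =", format(x$gamma_star, digits = digits),
      if (x$gamma_star == 0) "(equal-weight limit)" else "", "\n")
  cat("weighted dcor =", format(x$weighted_dcor, digits = digits),
      " (equal weights:", format(x$uniform_dcor, digits = digits), ")\n\n")
  print(x$ranking, digits = digits)
  invisible(x)
}

#' Log odds-ratio baseline ranking
#'
#' The classical univariate effect size: for each component the log odds
#' ratio of the group mean proportions between the two predictor groups
#' (second factor level versus first). Components are ranked by descending
#' absolute log OR. A group mean of 0 or 1 gives an infinite OR, which is
#' flagged with a warning.
#'
#' @param M Composition or count matrix, samples in rows.
#' @param groups Binary group labels; both groups must be nonempty.
#' @param pseudocount For count input containing zeros.
#' @return A `"codak_ranking"` whose `score` column is |log OR|; the signed
#'   values are kept in the `log_or` column.
#' @export
log_or_baseline <- function(M, groups, pseudocount = 1) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("'groups' must have exactly two levels")
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (is.null(colnames(M))) colnames(M) <- paste0("C", seq_len(ncol(M)))
  P <- if (is_whole(M) && max(M) > 1 + 1e-8)
    counts_to_composition(M, pseudocount = pseudocount) else closure(M)
  m2 <- colMeans(P[g == levels(g)[2L], , drop = FALSE])
  m1 <- colMeans(P[g == levels(g)[1L], , drop = FALSE])
  if (any(c(m1, m2) <= 0) || any(c(m1, m2) >= 1))
    warning("group mean proportion of 0 or 1: infinite odds ratio")
  lor <- log(m2 / (1 - m2)) - log(m1 / (1 - m1))
  rk <- new_ranking(colnames(P), abs(lor), "log_or",
                    extra = list(levels = levels(g)))
  rk$log_or <- lor[match(rk$component, colnames(P))]
  rk
}

#' Compare an estimated component ranking with the truth
#'
#' Computes the Spearman correlation between the estimated ranking and the
#' ranking of the absolute true log odds ratios, plus the overlap between
#' the estimated top-`top_m` set and the true top-`top_m` set. Ties on
#' either side receive average ranks (midranks), the canonical Spearman
#' convention -- important for the leave-one-out statistic, whose zero
#' clamp can tie many non-contributing components; the arbitrary
#' column-order tie-break stored in the ranking object would otherwise leak
#' into the correlation.
#'
#' @param ranking A `"codak_ranking"`, or a numeric vector of scores (larger
#'   = stronger) named like `true_log_or`.
#' @param true_log_or True per-component log odds ratios (signs are
#'   ignored).
#' @param top_m Size of the head compared (default 5).
#' @return List with `rank_correlation`, `top_overlap` and `top_m`.
#' @export
evaluate_ranking <- function(ranking, true_log_or, top_m = 5) {
  if (inherits(ranking, "codak_ranking")) {
    comp <- ranking$component
    score <- ranking$score
    est_rank <- ranking$rank
  } else {
    comp <- names(ranking) %||% as.character(seq_along(ranking))
    score <- as.numeric(ranking)
    ord <- order(-score)
    est_rank <- integer(length(ranking))
    est_rank[ord] <- seq_along(ranking)
  }
  truth <- true_log_or
  if (!is.null(names(truth))) {
    if (!all(comp %in% names(truth)))
      stop("component sets of ranking and truth do not match")
    truth <- truth[comp]
  } else if (length(truth) != length(comp)) {
    stop("component sets of ranking and truth do not match")
  }
  rho <- suppressWarnings(stats::cor(rank(-score, ties.method = "average"),
                                     rank(-abs(truth),
                                          ties.method = "average")))
  true_top <- comp[order(abs(truth), decreasing = TRUE)[seq_len(top_m)]]
  est_top <- comp[order(est_rank)[seq_len(top_m)]]
  list(rank_correlation = rho,
       top_overlap = length(intersect(est_top, true_top)),
       top_m = top_m)
}
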