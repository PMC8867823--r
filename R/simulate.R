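# Overdispersed multinomial-logit simulator for CyTOF-like cell-type counts
# and the size / power / ranking-recovery studies built on it.

#' Simulation configuration
#'
#' Describes one simulated two-group CyTOF study. Defaults reproduce the
#' reference design: 12 samples per group, 20 named cell types whose
#' baseline probabilities are log-spaced over \[0.002, 0.15\] (an unaffected
#' "other" category absorbs the remaining ~0.27 of probability mass and
#' serves as the multinomial-logit reference), 30,000-50,000 cells per
#' sample, and an observation-level random effect (OLRE) with standard
#' deviation 0.2 on every logit to model overdispersion.
#'
#' Effect patterns on the group-1 probabilities: `"all_small"` shifts all
#' named types by 0.2 percentage points, `"half_small"` every other type by
#' 0.2 pp, `"quarter_large"` five evenly spread types by 0.4 pp; signs
#' alternate along the affected set (smallest baseline gets "+") so the
#' probability vector needs at most a minimal re-closure and all entries
#' stay positive.
#'
#' @param n_per_group Samples per group (default 12).
#' @param q Number of named cell types (default 20).
#' @param cells_min,cells_max Range of the per-sample total cell count;
#'   totals are drawn uniformly on the integers of this range.
#' @param baseline_probs Optional custom baseline probabilities for the
#'   named types (strictly positive, sum < 1).
#' @param olre_sd Standard deviation of the observation-level random effect
#'   (default 0.2).
#' @param effect_pattern One of `"null"`, `"all_small"`, `"half_small"`,
#'   `"quarter_large"`.
#' @param effect_size Percentage-point difference for affected types;
#'   defaults to 0.2 (small patterns) or 0.4 (`"quarter_large"`).
#' @param scenario `"i"` (no covariate), `"ii"` (binary covariate, balanced
#'   within groups, with its own 0.2-pp shift on all named types) or
#'   `"iii"` (scenario ii plus repeated measures: each subject is observed
#'   under both covariate conditions with a shared subject-level random
#'   effect).
#' @param covariate_effect_size Percentage-point covariate shift (default
#'   0.2), scenarios ii/iii.
#' @param subject_re_sd Subject-level random-effect SD for scenario iii;
#'   default `sqrt(0.1)` there (the mild-correlation case), 0 otherwise.
#' @param n_sims Number of replicate datasets for the study drivers.
#' @param n_perms Permutations per test inside the study drivers.
#' @param alpha_grid Nominal levels at which rejection rates are reported.
#' @param seed Master seed; every replicate derives its own stream from it.
#' @return A `"codak_sim_config"` list.
#' @export
sim_config <- function(n_per_group = 12, q = 20, cells_min = 30000,
                       cells_max = 50000, baseline_probs = NULL,
                       olre_sd = 0.2,
                       effect_pattern = c("null", "all_small", "half_small",
                                          "quarter_large"),
                       effect_size = NULL, scenario = c("i", "ii", "iii"),
                       covariate_effect_size = 0.2, subject_re_sd = NULL,
                       n_sims = 2000, n_perms = 1000,
                       alpha_grid = c(0.01, 0.05, 0.1), seed = NULL) {
  effect_pattern <- match.arg(effect_pattern)
  scenario <- match.arg(scenario)
  if (is.null(effect_size))
    effect_size <- if (effect_pattern == "quarter_large") 0.4 else 0.2
  if (is.null(subject_re_sd))
    subject_re_sd <- if (scenario == "iii") sqrt(0.1) else 0
  if (is.null(baseline_probs))
    baseline_probs <- exp(seq(log(0.002), log(0.15), length.out = q))
  baseline_probs <- as.numeric(baseline_probs)
  if (length(baseline_probs) != q)
    stop("'baseline_probs' must have length q")
  if (any(baseline_probs <= 0) || sum(baseline_probs) >= 1)
    stop("'baseline_probs' must be strictly positive and sum to < 1 ",
         "(the remainder is the unaffected reference category)")
  if (scenario %in% c("ii", "iii") && n_per_group %% 2 != 0)
    stop("scenarios ii/iii need an even 'n_per_group' for a balanced ",
         "covariate")
  structure(list(n_per_group = n_per_group, q = q, cells_min = cells_min,
                 cells_max = cells_max, baseline_probs = baseline_probs,
                 olre_sd = olre_sd, effect_pattern = effect_pattern,
                 effect_size = effect_size, scenario = scenario,
                 covariate_effect_size = covariate_effect_size,
                 subject_re_sd = subject_re_sd, n_sims = n_sims,
                 n_perms = n_perms, alpha_grid = alpha_grid, seed = seed),
            class = "codak_sim_config")
}

#' @export
print.codak_sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  scenario %s, effect pattern %s (%.2g pp), %d per group, %d+1 cell types\n",
              x$scenario, x$effect_pattern, x$effect_size, x$n_per_group,
              x$q))
  cat(sprintf("  cells/sample %d-%d, OLRE sd %.3g, subject RE sd %.3g\n",
              x$cells_min, x$cells_max, x$olre_sd, x$subject_re_sd))
  cat(sprintf("  studies: %d replicates x %d permutations, master seed %s\n",
              x$n_sims, x$n_perms,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

# Indices (in baseline-ascending order, which is the storage order) of the
# components affected by each pattern, and the alternating signs.
affected_components <- function(q, pattern) {
  idx <- switch(pattern,
                null = integer(0),
                all_small = seq_len(q),
                half_small = seq(1L, q, by = 2L),
                quarter_large = unique(round(seq(1, q,
                                                 length.out = max(1L, round(q / 4))))))
  list(idx = idx, sign = rep_len(c(1, -1), length(idx)))
}

# Shift selected probabilities by +/- delta and re-close the full vector.
shift_probs <- function(p, idx, sgn, delta) {
  p[idx] <- p[idx] + sgn * delta
  if (any(p <= 0))
    stop("effect size too large for the baseline probabilities ",
         "(a probability became nonpositive)")
  p / sum(p)
}

#' Group probability vectors and true effects
#'
#' Builds the control-group and case-group cell-type probability vectors for
#' a configuration (named types plus the `"other"` reference) together with
#' the true per-component log odds ratios.
#'
#' @param config A [sim_config()] object.
#' @return List with `p0`, `p1` (probability vectors summing to 1),
#'   `true_log_or` (named, length q+1) and `affected` (indices of shifted
#'   named types).
#' @export
make_group_probs <- function(config) {
  stopifnot(inherits(config, "codak_sim_config"))
  q <- config$q
  nm <- c(sprintf("CT%02d", seq_len(q)), "other")
  p0 <- c(config$baseline_probs, 1 - sum(config$baseline_probs))
  names(p0) <- nm
  af <- affected_components(q, config$effect_pattern)
  p1 <- if (length(af$idx) == 0L) p0
        else shift_probs(p0, af$idx, af$sign, config$effect_size / 100)
  lor <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  list(p0 = p0, p1 = p1, true_log_or = lor, affected = af$idx)
}

#' True multivariate effect summaries
#'
#' The Aitchison distance between the two group probability vectors and the
#' largest absolute per-component log odds ratio -- the two scalar summaries
#' used to place a simulation scenario on an effect-size map.
#'
#' @param p0,p1 Probability vectors (summing to 1).
#' @return List with `true_ad` and `max_abs_log_or`.
#' @export
true_effect_summary <- function(p0, p1) {
  stopifnot(length(p0) == length(p1))
  lor <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  list(true_ad = sqrt(sum((clr_vec(p1) - clr_vec(p0))^2)),
       max_abs_log_or = max(abs(lor)))
}

#' Simulate one CyTOF-like dataset
#'
#' For each sample, a total cell count is drawn uniformly from
#' `[cells_min, cells_max]`, the group (and covariate) probability vector is
#' perturbed on the logit scale by an observation-level Gaussian random
#' effect (and, in scenario iii, a subject-level one shared across that
#' subject's two condition measurements), mapped through the softmax, and
#' counts are drawn from a multinomial. Fully deterministic given `seed`.
#'
#' @param config A [sim_config()] object.
#' @param seed Replicate seed (defaults to `config$seed`).
#' @return A list of class `"codak_sim_data"`: `counts` (n x (q+1) integer
#'   matrix), `x` (0/1 group), `z` (0/1 covariate or NULL), `subject`
#'   (subject ids or NULL), `truth` (from [make_group_probs()]) and
#'   `config`.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "codak_sim_config"))
  gp <- make_group_probs(config)
  q1 <- config$q + 1L
  npg <- config$n_per_group
  scen <- config$scenario

  if (scen == "iii") {
    n_subj <- 2L * npg
    subject <- rep(seq_len(n_subj), each = 2L)
    x <- rep(rep(0:1, each = npg), each = 2L)
    z <- rep(0:1, times = n_subj)
  } else {
    subject <- NULL
    x <- rep(0:1, each = npg)
    z <- if (scen == "ii") rep(rep(0:1, each = npg %/% 2L), times = 2L)
         else NULL
  }
  n <- length(x)

  # probability vector per (group, covariate) cell
  zeff <- affected_components(config$q, "all_small")
  pvec <- function(g, zv) {
    p <- if (g == 1) gp$p1 else gp$p0
    if (!is.null(z) && zv == 1)
      p <- shift_probs(p, zeff$idx, zeff$sign,
                       config$covariate_effect_size / 100)
    p
  }
  base_log <- lapply(0:1, function(g) lapply(0:1, function(zv)
    log(pvec(g, zv))))

  with_seed(seed, {
    totals <- config$cells_min +
      sample.int(config$cells_max - config$cells_min + 1L, n,
                 replace = TRUE) - 1L
    bsub <- if (scen == "iii" && config$subject_re_sd > 0)
      matrix(stats::rnorm(2L * npg * q1, 0, config$subject_re_sd),
             nrow = 2L * npg) else NULL
    counts <- matrix(0L, n, q1,
                     dimnames = list(paste0("S", seq_len(n)),
                                     names(gp$p0)))
    for (i in seq_len(n)) {
      eta <- base_log[[x[i] + 1L]][[if (is.null(z)) 1L else z[i] + 1L]] +
        stats::rnorm(q1, 0, config$olre_sd)
      if (!is.null(bsub)) eta <- eta + bsub[subject[i], ]
      pr <- exp(eta - max(eta))
      counts[i, ] <- stats::rmultinom(1L, totals[i], pr)
    }
    structure(list(counts = counts, x = x, z = z, subject = subject,
                   truth = gp, config = config),
              class = "codak_sim_data")
  })
}

# ---- study drivers ----------------------------------------------------------

sim_method_pvalue <- function(method, comp, dat, n_perms, seed) {
  x <- dat$x
  switch(method,
    codak_ad = codak_fit_plain(comp, x, "ad_gaussian", "binary", "median",
                               n_perms, seed)$p.value,
    codak_ad_linear = codak_fit_plain(comp, x, "ad_linear", "binary",
                                      "median", n_perms, seed)$p.value,
    codak_bc = codak_fit_plain(comp, x, "bc", "binary", "median", n_perms,
                               seed)$p.value,
    codak_ed = codak_fit_plain(comp, x, "euclidean", "binary", "median",
                               n_perms, seed)$p.value,
    codak_alr_kc = codak_fit_alr(comp, x, factor(dat$z), "kennedy_cade",
                                 "ad_gaussian", "binary", "median", n_perms,
                                 seed, ncol(comp))$p.value,
    codak_alr_fl = codak_fit_alr(comp, x, factor(dat$z), "freedman_lane",
                                 "ad_gaussian", "binary", "median", n_perms,
                                 seed, ncol(comp))$p.value,
    codak_sk = codak_fit_sk(comp, x, factor(dat$z), "ad_gaussian", "binary",
                            "median", n_perms, seed)$p.value,
    stop("unknown method: ", method))
}

#' Size / power study
#'
#' Simulates `config$n_sims` datasets, applies each requested test, and
#' summarizes rejection rates at every nominal level with Monte Carlo
#' standard errors `sqrt(p(1-p)/n_sims)`.
#'
#' @param config A [sim_config()] object; `effect_pattern = "null"` gives a
#'   size study, anything else a power study.
#' @param methods Character vector from `codak_ad`, `codak_ad_linear`,
#'   `codak_bc`, `codak_ed`, `codak_alr_kc`, `codak_alr_fl`, `codak_sk`
#'   (the covariate-adjusted ones need scenario ii or iii).
#' @param seed Master seed (defaults to `config$seed`).
#' @return A `"codak_sim_summary"` with the rejection-rate table, its
#'   standard errors and the full p-value matrix.
#' @export
run_size_power_study <- function(config, methods = "codak_ad",
                                 seed = config$seed) {
  stopifnot(inherits(config, "codak_sim_config"))
  needs_z <- c("codak_alr_kc", "codak_alr_fl", "codak_sk")
  if (any(methods %in% needs_z) && config$scenario == "i")
    stop("covariate-adjusted methods need scenario ii or iii")
  ns <- config$n_sims
  sim_seeds <- derive_seeds(seed, 2L * ns)
  pmat <- matrix(NA_real_, ns, length(methods),
                 dimnames = list(NULL, methods))
  for (r in seq_len(ns)) {
    dat <- simulate_dataset(config, seed = sim_seeds[r])
    comp <- counts_to_composition(dat$counts, pseudocount = 1)
    for (m in methods)
      pmat[r, m] <- sim_method_pvalue(m, comp, dat, config$n_perms,
                                      sim_seeds[ns + r])
  }
  alpha <- config$alpha_grid
  rej <- sapply(alpha, function(a) colMeans(pmat <= a))
  rej <- matrix(rej, nrow = length(methods),
                dimnames = list(methods, paste0("alpha_", alpha)))
  se <- sqrt(rej * (1 - rej) / ns)
  structure(list(rejection = rej, se = se, p_values = pmat,
                 alpha_grid = alpha, n_sims = ns, config = config),
            class = "codak_sim_summary")
}

#' @export
print.codak_sim_summary <- function(x, digits = 3, ...) {
  cat("Rejection rates over", x$n_sims, "simulated datasets\n")
  cat("(", x$config$scenario, "scenario,", x$config$effect_pattern,
      "effect pattern;", x$config$n_perms, "permutations per test )\n\n")
  tab <- round(x$rejection, digits)
  print(tab)
  cat("\nMonte Carlo standard errors:\n")
  print(round(x$se, digits))
  invisible(x)
}

# Restrict a ranking to a component subset and re-rank within it.
restrict_ranking <- function(rk, keep) {
  sel <- rk$component %in% keep
  new_ranking(rk$component[sel], rk$score[sel], attr(rk, "method"))
}

#' Ranking-recovery study
#'
#' Simulates non-null datasets (cycling through the requested effect
#' patterns), ranks the cell types by the leave-one-out dcor, the optimized
#' weighted dcor and the estimated log odds ratio, and evaluates each
#' ranking against the true log odds ratios over the named cell types
#' (Spearman rank correlation and top-`top_m` overlap). No permutations are
#' needed.
#'
#' @param config A [sim_config()] object; `n_sims` replicates are split
#'   across `cases`.
#' @param cases Non-null effect patterns cycled over (default all three).
#' @param methods Ranking methods: subset of `"loo"`, `"wdcor"`, `"logor"`.
#' @param top_m Head size for the overlap metric (default 5).
#' @param seed Master seed (defaults to `config$seed`).
#' @return A `"codak_ranking_summary"`: per-replicate results and
#'   per-method medians (pooled and per case).
#' @export
run_ranking_study <- function(config,
                              cases = c("all_small", "half_small",
                                        "quarter_large"),
                              methods = c("loo", "wdcor", "logor"),
                              top_m = 5, seed = config$seed) {
  stopifnot(inherits(config, "codak_sim_config"))
  if (any(cases == "null")) stop("ranking recovery needs non-null patterns")
  ns <- config$n_sims
  sim_seeds <- derive_seeds(seed, ns)
  cfgs <- lapply(cases, function(cs)
    sim_config(n_per_group = config$n_per_group, q = config$q,
               cells_min = config$cells_min, cells_max = config$cells_max,
               baseline_probs = config$baseline_probs,
               olre_sd = config$olre_sd, effect_pattern = cs,
               scenario = "i", n_sims = 1L, n_perms = config$n_perms))
  named <- sprintf("CT%02d", seq_len(config$q))
  rows <- vector("list", ns * length(methods))
  k <- 0L
  for (r in seq_len(ns)) {
    ci <- ((r - 1L) %% length(cases)) + 1L
    dat <- simulate_dataset(cfgs[[ci]], seed = sim_seeds[r])
    comp <- counts_to_composition(dat$counts, pseudocount = 1)
    truth <- dat$truth$true_log_or[named]
    for (m in methods) {
      rk <- switch(m,
                   loo = loo_dcor(comp, dat$x),
                   wdcor = weighted_dcor_rank(comp, dat$x)$ranking,
                   logor = log_or_baseline(comp, dat$x),
                   stop("unknown ranking method: ", m))
      ev <- evaluate_ranking(restrict_ranking(rk, named), truth,
                             top_m = top_m)
      k <- k + 1L
      rows[[k]] <- data.frame(sim = r, case = cases[ci], method = m,
                              rank_correlation = ev$rank_correlation,
                              top_overlap = ev$top_overlap,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(split(res, res$method), function(d)
    data.frame(method = d$method[1L],
               median_rank_correlation = stats::median(d$rank_correlation),
               median_top_overlap = stats::median(d$top_overlap),
               stringsAsFactors = FALSE)))
  med <- med[match(methods, med$method), , drop = FALSE]
  rownames(med) <- NULL
  structure(list(results = res, medians = med,
                 pooled_median_overlap = stats::median(res$top_overlap),
                 top_m = top_m, cases = cases, n_sims = ns, config = config),
            class = "codak_ranking_summary")
}

#' @export
print.codak_ranking_summary <- function(x, digits = 3, ...) {
  cat("Ranking recovery over", x$n_sims, "simulated datasets (cases:",
      paste(x$cases, collapse = ", "), ")\n\n")
  med <- x$medians
  med$median_rank_correlation <- round(med$median_rank_correlation, digits)
  print(med, row.names = FALSE)
  cat("\npooled median top-", x$top_m, " overlap: ",
      x$pooled_median_overlap, "\n", sep = "")
  invisible(x)
}
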