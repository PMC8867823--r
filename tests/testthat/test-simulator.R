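test_that("group probability vectors implement the stated effect patterns", {
  cfg <- sim_config(effect_pattern = "null")
  gp <- make_group_probs(cfg)
  expect_equal(gp$p0, gp$p1)
  expect_equal(unname(gp$true_log_or), rep(0, 21))
  expect_equal(sum(gp$p0), 1)
  expect_equal(range(gp$p0[1:20]), c(0.002, 0.15))

  # a 0.2 percentage-point raise of a 0.05 baseline: direct log OR
  cfg2 <- sim_config(q = 4, baseline_probs = c(0.05, 0.06, 0.07, 0.08),
                     effect_pattern = "all_small")
  gp2 <- make_group_probs(cfg2)
  expect_equal(unname(gp2$p1["CT01"]), 0.052)
  expect_equal(unname(gp2$true_log_or["CT01"]),
               log((0.052 / 0.948) / (0.05 / 0.95)), tolerance = 1e-12)
  expect_equal(unname(gp2$true_log_or["CT01"]), 0.041327, tolerance = 1e-4)
  expect_equal(sum(gp2$p1), 1)
  expect_equal(unname(gp2$true_log_or["other"]), 0)

  # alternating signs: half the affected components move down
  cfgd <- sim_config(effect_pattern = "quarter_large")
  gpd <- make_group_probs(cfgd)
  expect_length(gpd$affected, 5)
  expect_true(all(gpd$p1 > 0))
  # an effect too large for the baseline is refused
  expect_error(make_group_probs(
    sim_config(q = 4, baseline_probs = c(0.01, 0.001, 0.02, 0.03),
               effect_pattern = "all_small", effect_size = 0.2)),
    "too large")
})

test_that("simulate_dataset is deterministic and respects its margins", {
  cfg <- sim_config(effect_pattern = "half_small", n_per_group = 6)
  d1 <- simulate_dataset(cfg, seed = 31)
  d2 <- simulate_dataset(cfg, seed = 31)
  expect_identical(d1$counts, d2$counts)
  d3 <- simulate_dataset(cfg, seed = 32)
  expect_false(identical(d1$counts, d3$counts))
  tot <- rowSums(d1$counts)
  expect_true(all(tot >= 30000 & tot <= 50000))
  expect_equal(dim(d1$counts), c(12, 21))
  expect_equal(d1$x, rep(0:1, each = 6))
})

test_that("without overdispersion the sample compositions match the truth", {
  cfg <- sim_config(effect_pattern = "null", n_per_group = 100, olre_sd = 0)
  d <- simulate_dataset(cfg, seed = 5)
  comp <- counts_to_composition(d$counts)
  mbar <- colMeans(comp)
  se <- apply(comp, 2, sd) / sqrt(nrow(comp))
  expect_true(all(abs(mbar - d$truth$p0) <= 3 * se + 1e-6))
})

test_that("the OLRE term produces detectable overdispersion", {
  cfg0 <- sim_config(effect_pattern = "null", n_per_group = 100, olre_sd = 0)
  cfg2 <- sim_config(effect_pattern = "null", n_per_group = 100,
                     olre_sd = 0.2)
  v0 <- apply(log(counts_to_composition(
    simulate_dataset(cfg0, seed = 6)$counts)), 2, var)
  v2 <- apply(log(counts_to_composition(
    simulate_dataset(cfg2, seed = 6)$counts)), 2, var)
  # log-proportion variance well above the multinomial-only level,
  # approaching the OLRE variance of 0.04
  expect_true(all(v2 > 2.5 * v0))
  expect_gt(median(v2), 0.02)
})

test_that("covariate and repeated-measures designs have the right structure", {
  cfg2 <- sim_config(scenario = "ii", effect_pattern = "null")
  d2 <- simulate_dataset(cfg2, seed = 7)
  expect_equal(length(d2$z), 24)
  expect_equal(as.vector(tapply(d2$z, d2$x, mean)), c(0.5, 0.5))  # balanced
  cfg3 <- sim_config(scenario = "iii", effect_pattern = "null")
  expect_equal(cfg3$subject_re_sd, sqrt(0.1))
  d3 <- simulate_dataset(cfg3, seed = 8)
  expect_equal(nrow(d3$counts), 48)
  expect_equal(unname(table(d3$subject)), rep(2L, 24), ignore_attr = TRUE)
  # x constant within subject, z varies within subject
  expect_true(all(tapply(d3$x, d3$subject, function(v) length(unique(v))) == 1))
  expect_true(all(tapply(d3$z, d3$subject, sum) == 1))
})

test_that("size/power driver returns coherent, monotone rejection tables", {
  cfg <- sim_config(effect_pattern = "null", n_per_group = 6, n_sims = 40,
                    n_perms = 99, seed = 88)
  s <- run_size_power_study(cfg, methods = c("codak_ad", "codak_ed"))
  expect_equal(dim(s$rejection), c(2, 3))
  expect_true(all(s$p_values > 0 & s$p_values <= 1))
  # rejection nondecreasing in alpha
  expect_true(all(apply(s$rejection, 1, function(r) all(diff(r) >= 0))))
  expect_equal(s$se, sqrt(s$rejection * (1 - s$rejection) / 40))
  # reproducible from the master seed
  s2 <- run_size_power_study(cfg, methods = c("codak_ad", "codak_ed"))
  expect_identical(s$p_values, s2$p_values)
})

test_that("ranking driver recovers a perfect-information control", {
  cfg <- sim_config(n_sims = 9, seed = 21)
  rs <- run_ranking_study(cfg, cases = c("all_small", "quarter_large"))
  expect_equal(nrow(rs$results), 9 * 3)
  expect_true(all(rs$results$top_overlap >= 0 & rs$results$top_overlap <= 5))
  expect_true(all(abs(rs$results$rank_correlation) <= 1))
  # ranking by the true log OR itself is perfect
  gp <- make_group_probs(sim_config(effect_pattern = "quarter_large"))
  named <- gp$true_log_or[1:20]
  ev <- evaluate_ranking(setNames(abs(named), names(named)), named)
  expect_equal(ev$rank_correlation, 1)
  expect_equal(ev$top_overlap, 5)
})

test_that("true effect summaries behave like their definitions", {
  p <- closure(c(1, 2, 3, 4))
  expect_equal(true_effect_summary(p, p), list(true_ad = 0,
                                               max_abs_log_or = 0))
  gp <- make_group_probs(sim_config(effect_pattern = "quarter_large"))
  te <- true_effect_summary(gp$p0, gp$p1)
  expect_gt(te$true_ad, 0)
  expect_gt(te$max_abs_log_or, 0)
  # invariant to a joint reordering of the components
  perm <- sample(length(gp$p0))
  te2 <- true_effect_summary(gp$p0[perm], gp$p1[perm])
  expect_equal(te2$true_ad, te$true_ad, tolerance = 1e-12)
  expect_equal(te2$max_abs_log_or, te$max_abs_log_or, tolerance = 1e-12)
})
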