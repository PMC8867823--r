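test_that("the trace form equals the brute-force double-centering oracle", {
  set.seed(21)
  for (n in c(5, 8, 10)) {
    K <- crossprod(matrix(rnorm(n * n), n))
    L <- crossprod(matrix(rnorm(n * n), n))
    expect_equal(kdc_statistic(K, L), kdc_oracle(K, L), tolerance = 1e-10)
    # explicit trace identity
    H <- diag(n) - 1 / n
    expect_equal(kdc_statistic(K, L),
                 sum(diag(K %*% H %*% L %*% H)) / n^2, tolerance = 1e-10)
  }
  expect_error(kdc_statistic(diag(3), diag(4)), "dimensions")
})

test_that("the statistic vanishes for constant kernels and is nonnegative", {
  set.seed(22)
  K <- gaussian_kernel(aitchison_dist(rand_comp(8, 5)))
  expect_equal(kdc_statistic(K, matrix(3.7, 8, 8)), 0, tolerance = 1e-14)
  expect_gte(kdc_statistic(K, K), 0)
})

test_that("dcor normalizes to [0,1], peaks at self, ignores constants", {
  set.seed(23)
  P <- rand_comp(10, 6)
  K <- gaussian_kernel(aitchison_dist(P))
  L <- predictor_kernel(rep(0:1, 5))
  expect_equal(kdc_dcor(K, K), 1, tolerance = 1e-12)
  d <- kdc_dcor(K, L)
  expect_true(d >= 0 && d <= 1 + 1e-8)
  expect_equal(kdc_dcor(K, L + 5), d, tolerance = 1e-10)
  expect_error(kdc_dcor(K, matrix(1, 10, 10)), "predictor kernel")
  # independence: small average dcor at n = 50
  set.seed(24)
  vals <- replicate(20, {
    kdc_dcor(gaussian_kernel(aitchison_dist(rand_comp(50, 5))),
             predictor_kernel(rnorm(50), kind = "continuous"))
  })
  expect_lt(mean(vals), 0.2)
})

test_that("dcor with L2-distance kernels is the squared Szekely dcor", {
  set.seed(25)
  for (rep in 1:5) {
    x <- matrix(rnorm(12 * 3), 12, 3)
    y <- rnorm(12)
    K <- dist_kernel(as.matrix(dist(x)), squared = FALSE)
    L <- dist_kernel(as.matrix(dist(y)), squared = FALSE)
    expect_equal(kdc_dcor(K, L), szekely_dcor2(x, y), tolerance = 1e-8)
  }
})

test_that("permutation test is valid, deterministic, and exact for tiny n", {
  set.seed(26)
  P <- rand_comp(12, 5)
  K <- gaussian_kernel(aitchison_dist(P))
  x <- rep(0:1, 6)
  L <- predictor_kernel(x)
  r1 <- kdc_perm_test(K, L, B = 300, seed = 99)
  r2 <- kdc_perm_test(K, L, B = 300, seed = 99)
  expect_identical(r1$p.value, r2$p.value)
  expect_identical(r1$perm_stats, r2$perm_stats)
  expect_gte(r1$p.value, 1 / 301)
  # constant predictor kernel: every permutation ties the observed value
  expect_equal(kdc_perm_test(K, matrix(1, 12, 12), B = 100,
                             seed = 1)$p.value, 1)
  # n = 5: all 120 permutations enumerated
  r <- kdc_perm_test(K[1:5, 1:5], L[1:5, 1:5], B = 10, seed = 1)
  expect_true(r$exact)
  expect_equal(r$n_perm, 120)
  expect_gte(r$p.value, 1 / 120)
  expect_error(kdc_perm_test(K[1:2, 1:2], L[1:2, 1:2]), "at least 3")
})

test_that("codak is invariant to a joint relabeling of samples", {
  set.seed(27)
  d <- tiny_two_group(8, closure(1:6), closure(6:1))
  comp <- counts_to_composition(d$counts)
  f1 <- codak(comp, d$x, n_perm = 200, seed = 5)
  perm <- sample(16)
  f2 <- codak(comp[perm, ], d$x[perm], n_perm = 200, seed = 5)
  expect_equal(f2$statistic, f1$statistic, tolerance = 1e-12)
  expect_equal(f2$dcor, f1$dcor, tolerance = 1e-12)
  # with n! small the permutations are enumerated, so even the p-value is
  # exactly invariant under the relabeling
  d6 <- tiny_two_group(3, closure(1:6), closure(6:1))
  c6 <- counts_to_composition(d6$counts)
  g1 <- codak(c6, d6$x, n_perm = 50, seed = 2)
  pm <- sample(6)
  g2 <- codak(c6[pm, ], d6$x[pm], n_perm = 50, seed = 2)
  expect_true(g1$exact && g1$n_perm == 720)
  expect_identical(g2$p.value, g1$p.value)
})

test_that("the formula interface matches the default method", {
  set.seed(28)
  d <- tiny_two_group(6, closure(1:5), closure(1:5))
  comp <- counts_to_composition(d$counts)
  df <- data.frame(grp = factor(d$x), batch = rep(c("p", "q"), 6))
  f1 <- codak(comp, df$grp, n_perm = 100, seed = 3)
  f2 <- codak(comp ~ grp, data = df, n_perm = 100, seed = 3)
  expect_equal(f2$statistic, f1$statistic)
  expect_identical(f2$p.value, f1$p.value)
  f3 <- codak(comp ~ grp + batch, data = df, n_perm = 50, seed = 3)
  expect_equal(f3$adjustment, "alr_fl")
  f4 <- codak(comp ~ grp, data = df, strata = batch, n_perm = 50, seed = 3)
  expect_equal(f4$adjustment, "stratified")
  expect_output(print(f1), "Kernel distance covariance")
  s <- summary(f1)
  expect_s3_class(s, "summary.codak")
  expect_output(print(s), "null quantiles")
})

test_that("null p-values are super-uniform and the two AD kernels agree", {
  # empirical check of P(p <= a) <= a + 2*sqrt(a(1-a)/N) under the null,
  # and of the near-identical rejection behavior of the gaussian and
  # distance-induced Aitchison kernels
  set.seed(29)
  N <- 250
  p0 <- closure(exp(seq(log(0.01), log(0.3), length.out = 8)))
  pv <- t(replicate(N, {
    d <- tiny_two_group(10, p0, p0, total = 2000)
    comp <- counts_to_composition(d$counts)
    D <- aitchison_dist(comp)
    L <- predictor_kernel(d$x)
    s <- sample.int(1e6, 1)   # shared permutations isolate the kernel choice
    c(gauss = kdc_perm_test(gaussian_kernel(D), L, B = 399,
                            seed = s)$p.value,
      lin = kdc_perm_test(dist_kernel(D), L, B = 399, seed = s)$p.value)
  }))
  for (a in c(0.01, 0.05, 0.1)) {
    bound <- a + 2 * sqrt(a * (1 - a) / N)
    expect_lte(mean(pv[, "gauss"] <= a), bound)
    expect_lte(mean(pv[, "lin"] <= a), bound)
  }
  agree <- mean((pv[, "gauss"] <= 0.05) == (pv[, "lin"] <= 0.05))
  expect_gte(agree, 0.95)
})
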