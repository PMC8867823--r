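test_that("Aitchison distance matches the clr form and the double-sum form", {
  P <- rbind(c(0.5, 0.25, 0.25), c(0.25, 0.5, 0.25))
  D <- aitchison_dist(P)
  expect_equal(D[1, 2], sqrt(2) * log(2), tolerance = 1e-12)
  expect_equal(D[1, 1], 0)
  set.seed(7)
  Q <- rand_comp(5, 4)
  expect_lt(max(abs(aitchison_dist(Q) - ad_doublesum_oracle(Q))), 1e-8)
})

test_that("Aitchison distance has the simplex-geometry properties", {
  set.seed(8)
  P <- rand_comp(6, 5)
  D <- aitchison_dist(P)
  expect_lt(max(abs(D - t(D))), 1e-12)
  # scale invariance: rescale one unclosed row by 7
  S <- P; S[2, ] <- 7 * S[2, ]
  expect_equal(aitchison_dist(S), D, tolerance = 1e-12)
  # permutation invariance under a joint column permutation
  perm <- sample(ncol(P))
  expect_equal(aitchison_dist(P[, perm]), D, tolerance = 1e-12)
  # triangle inequality on all triples
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  # subcompositional dominance: dropping any component shrinks distances
  for (cc in seq_len(ncol(P))) {
    Dc <- aitchison_dist(drop_component(P, cc))
    expect_true(all(Dc <= D + 1e-10))
  }
})

test_that("weighted Aitchison distance generalizes the unweighted one", {
  set.seed(9)
  P <- rand_comp(5, 6)
  D <- aitchison_dist(P)
  expect_equal(weighted_aitchison_dist(P, rep(1, 6)), D, tolerance = 1e-12,
               ignore_attr = TRUE)
  w <- rexp(6) + 0.1
  Dw <- weighted_aitchison_dist(P, w)
  expect_equal(weighted_aitchison_dist(P, 2 * w)^2, 2 * Dw^2,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(diag(Dw), rep(0, 5), ignore_attr = TRUE)
  expect_error(weighted_aitchison_dist(P, c(1, 1, 1, 1, 1, 0)), "positive")
})

test_that("Bray-Curtis handles zeros and hits its closed-form values", {
  M <- rbind(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5))
  expect_equal(bray_curtis_dist(M)[1, 2], 0.5)
  disjoint <- rbind(c(1, 0), c(0, 1))
  expect_equal(bray_curtis_dist(disjoint)[1, 2], 1)
  expect_equal(bray_curtis_dist(M)[1, 1], 0)
  set.seed(10)
  P <- rand_comp(6, 4)
  expect_true(all(bray_curtis_dist(P) >= 0 & bray_curtis_dist(P) <= 1))
})

test_that("Euclidean distance agrees with the clr route to Aitchison", {
  expect_equal(euclidean_dist(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  set.seed(11)
  P <- rand_comp(5, 4)
  expect_equal(euclidean_dist(clr(P)), aitchison_dist(P), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("distance-induced kernel is the double-centered Gram matrix", {
  n <- 6
  expect_equal(dist_kernel(matrix(0, n, n)), matrix(0, n, n),
               ignore_attr = TRUE)
  set.seed(12)
  X <- matrix(rnorm(n * 3), n, 3)
  K <- dist_kernel(as.matrix(dist(X)), squared = TRUE)
  H <- diag(n) - 1 / n
  expect_equal(K, H %*% X %*% t(X) %*% H, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(K))), 1e-8)
  # PSD for Aitchison distances (Euclidean-embeddable via clr)
  P <- rand_comp(8, 5)
  ev <- eigen(dist_kernel(aitchison_dist(P)), symmetric = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("gaussian kernel resolves the median bandwidth and decays", {
  D <- as.matrix(dist(c(0, 1, 3, 7)))
  K <- gaussian_kernel(D, gamma = 2)
  expect_equal(diag(K), rep(1, 4), ignore_attr = TRUE)
  expect_equal(K[1, 2], exp(-0.5))
  g <- median(D[upper.tri(D)])
  expect_equal(attr(gaussian_kernel(D), "gamma"), g)
  D3 <- as.matrix(dist(c(0, 1, 3)))      # pair distances 1, 2, 3: median 2
  expect_equal(gaussian_kernel(D3)[2, 3], exp(-1))
  # strictly decreasing in distance
  ut <- upper.tri(D)
  expect_true(all(order(K[ut]) == order(-D[ut])))
  expect_error(gaussian_kernel(matrix(0, 3, 3)), "degenerate")
})

test_that("predictor kernel covers binary and continuous cases", {
  L <- predictor_kernel(c("a", "b", "a", "b"))
  expect_equal(attr(L, "kind"), "binary")
  expect_equal(L[1, 3], 1)
  expect_equal(L[1, 2], exp(-1))
  # PSD: Gaussian kernel on a metric
  set.seed(13)
  g <- sample(0:1, 12, replace = TRUE)
  ev <- eigen(predictor_kernel(g, kind = "binary"), symmetric = TRUE)$values
  expect_gt(min(ev), -1e-10)
  Lc <- predictor_kernel(c(1, -1), kind = "continuous", scale = FALSE)
  expect_equal(unclass(Lc), rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  expect_error(predictor_kernel(c(1, 2, 3), kind = "binary"), "levels")
})

test_that("stratified kernel masks across strata and stays PD", {
  set.seed(14)
  P <- rand_comp(10, 5)
  K <- gaussian_kernel(aitchison_dist(P))
  expect_equal(stratify_kernel(K, rep("s", 10)), K, ignore_attr = TRUE)
  expect_warning(K1 <- stratify_kernel(K, paste0("s", 1:10)), "size 1")
  expect_equal(unclass(K1), diag(10), ignore_attr = TRUE)
  st <- rep(c("u", "v"), each = 5)
  Ks <- stratify_kernel(K, st)
  expect_true(all(Ks[st == "u", st == "v"] == 0))
  expect_equal(Ks[1:5, 1:5], K[1:5, 1:5], ignore_attr = TRUE)
  expect_gt(min(eigen(Ks, symmetric = TRUE)$values), 0)
})

test_that("psd_clip projects onto the PSD cone and flags itself", {
  set.seed(15)
  A <- crossprod(matrix(rnorm(25), 5, 5))
  expect_equal(psd_clip(A), A, tolerance = 1e-8, ignore_attr = TRUE)
  expect_false(attr(psd_clip(A), "psd_clipped"))
  B <- diag(c(1, -1))
  Bc <- psd_clip(B)
  expect_true(attr(Bc, "psd_clipped"))
  expect_equal(unclass(Bc), diag(c(1, 0)), ignore_attr = TRUE)
  # spectral projection oracle: nearest PSD among spectral truncations
  S <- matrix(rnorm(36), 6, 6); S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  proj <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  expect_equal(unclass(psd_clip(S)), proj, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gt(min(eigen(psd_clip(S), symmetric = TRUE)$values), -1e-8)
})
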