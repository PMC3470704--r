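test_that("Cohen's d matches the pooled-SD formula and is antisymmetric", {
  expect_equal(cohens_d(c(3, 4, 5), c(1, 2, 3)), 2)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # invariant to adding a constant
  set.seed(1)
  a <- rnorm(10); b <- rnorm(12)
  expect_equal(cohens_d(a, b), cohens_d(a + 7, b + 7))
  expect_warning(d <- cohens_d(rep(1, 5), rep(1, 5)), "zero pooled SD")
  expect_true(is.na(d))
})

test_that("corrected effect sizes are orthogonal residuals that recover noise", {
  set.seed(2)
  r <- runif(200, -0.8, 0.8)
  eps <- rnorm(200, sd = 0.3)
  d <- 2 * r + eps
  res <- corrected_effect_sizes(d, r)
  expect_lt(abs(cor(res, r)), 1e-10)
  expect_lt(abs(mean(res)), 1e-10)
  expect_gt(cor(res, eps), 0.99)
  # perfectly linear d leaves zero residuals
  expect_lt(max(abs(corrected_effect_sizes(2 * r + 1, r))), 1e-10)
  expect_warning(corrected_effect_sizes(d, rep(0.5, 200)), "constant")
})

test_that("group effect comparison detects a shifted gene group", {
  set.seed(3)
  res <- c(rnorm(100), rnorm(100, mean = 1))
  names(res) <- paste0("g", 1:200)
  groups <- list(up = paste0("g", 101:200), down = paste0("g", 1:100))
  out <- group_effect_comparison(res, groups)
  expect_lt(out$p, 0.01)
  # label shuffles are approximately uniform: check a small batch
  ps <- replicate(50, {
    idx <- sample(200, 100)
    group_effect_comparison(res, list(a = paste0("g", idx),
                                      b = paste0("g", setdiff(1:200, idx))))$p
  })
  expect_lt(mean(ps < 0.05), 0.2)
  expect_error(group_effect_comparison(res, list(a = "gX", b = "g1")),
               "empty gene group")
})

test_that("variance F-test is calibrated, powered, and inverts on swap", {
  set.seed(4)
  n <- 20
  agesA <- runif(n, 20, 99); agesB <- runif(n, 20, 99)
  # calibration on equal-variance nulls
  ps <- replicate(400, {
    vA <- 0.03 * agesA + rnorm(n, sd = 0.3)
    vB <- 0.03 * agesB + rnorm(n, sd = 0.3)
    variance_f_test(vA, vB, agesA, agesB)$p_A_greater
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  # power at 4x variance inflation in A: detrending spends 2-4 df, so the
  # exact F power at n = 20 is ~0.88; assert a bound clear of Monte Carlo
  # noise
  hits <- replicate(400, {
    vA <- 0.03 * agesA + rnorm(n, sd = 0.6)
    vB <- 0.03 * agesB + rnorm(n, sd = 0.3)
    variance_f_test(vA, vB, agesA, agesB)$p_A_greater < 0.05
  })
  expect_gte(mean(hits), 0.8)
  # swapping groups inverts F
  vA <- 0.03 * agesA + rnorm(n, sd = 0.5)
  vB <- 0.03 * agesB + rnorm(n, sd = 0.25)
  f1 <- variance_f_test(vA, vB, agesA, agesB)
  f2 <- variance_f_test(vB, vA, agesB, agesA)
  expect_equal(f1$F, 1 / f2$F, tolerance = 1e-12)
  expect_equal(f1$p_A_greater, f2$p_B_greater, tolerance = 1e-12)
  # detrending matters: divergent trajectories are not dispersion
  vA2 <- 0.10 * agesA + rnorm(n, sd = 0.3)
  vB2 <- 0.02 * agesB + rnorm(n, sd = 0.3)
  raw <- variance_f_test(vA2, vB2, detrend = FALSE)
  det <- variance_f_test(vA2, vB2, agesA, agesB)
  expect_gt(raw$F, det$F)
})

test_that("hypergeometric overlap matches enumeration and the worked case", {
  u <- paste0("g", 1:20)
  res <- hypergeometric_overlap(u[1:10], u[1:10], u)
  expect_equal(res$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$overlap, 10)

  # full set vs full set is degenerate with p = 1
  expect_equal(hypergeometric_overlap(u, u, u)$p, 1)

  # random configurations vs exhaustive enumeration
  set.seed(5)
  for (r in 1:25) {
    N <- sample(5:25, 1)
    uu <- paste0("x", seq_len(N))
    A <- sample(uu, sample(1:N, 1))
    B <- sample(uu, sample(1:N, 1))
    got <- hypergeometric_overlap(A, B, uu)
    want <- enum_hyper_tail(length(intersect(A, B)), length(A),
                            length(B), N)
    expect_equal(got$p, want, tolerance = 1e-10)
  }

  # independence-scale overlap gives odds ratio near 1
  set.seed(6)
  big <- paste0("y", 1:4000)
  A <- sample(big, 2000)
  B <- sample(big, 2000)
  expect_lt(abs(log(hypergeometric_overlap(A, B, big)$odds_ratio)), 0.25)
  expect_error(hypergeometric_overlap("a", "b", character(0)), "empty")
})

test_that("gene clustering recovers planted archetypes and ignores order", {
  set.seed(7)
  grid <- seq(20, 90, length.out = 30)
  up <- t(replicate(20, scale(grid)[, 1] + rnorm(30, sd = 0.2)))
  down <- t(replicate(20, -scale(grid)[, 1] + rnorm(30, sd = 0.2)))
  feats <- rbind(up, down)
  rownames(feats) <- paste0("g", 1:40)
  lab <- cluster_genes(feats, k = 2)
  expect_identical(length(unique(lab[1:20])), 1L)
  expect_identical(length(unique(lab[21:40])), 1L)
  expect_false(lab[1] == lab[40])
  # permuted input recovers the same partition up to label names
  perm <- sample(40)
  lab2 <- cluster_genes(feats[perm, ], k = 2)
  expect_true(all(outer(lab, lab, "==") ==
                  outer(lab2[rownames(feats)], lab2[rownames(feats)], "==")))
  # duplicated rows land together; k = 1 is a single cluster
  expect_identical(unname(cluster_genes(feats[c(1, 1, 30), ], 2)[1:2]),
                   c(1L, 1L))
  expect_true(all(cluster_genes(feats, 1) == 1))
  expect_error(cluster_genes(feats, 41), "exceeds")
})

test_that("bootstrap sample clustering separates a planted subpopulation", {
  cfg <- onset_shift_config(n_genes = 120, delta = 10, seed = 31,
                            subpopulation_fraction = 0.5)
  sim <- generate_dataset(cfg)
  sub <- attr(sim$truth, "subpop_samples")
  bc <- bootstrap_cluster_samples(sim$dataset, n_boot = 150, seed = 7)
  # the planted subgroup is one consensus cluster on its own
  expect_identical(length(unique(bc$partition[sub])), 1L)
  others <- setdiff(names(bc$partition), sub)
  expect_false(any(bc$partition[others] == bc$partition[sub][1]))
  # and it is stable under gene resampling
  pairs <- combn(sub, 2)
  expect_gte(mean(bc$stability[cbind(pairs[1, ], pairs[2, ])]), 0.9)
  # determinism
  bc2 <- bootstrap_cluster_samples(sim$dataset, n_boot = 150, seed = 7)
  expect_identical(bc$stability, bc2$stability)
})
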