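test_that("identity curves align along the diagonal with zero cost", {
  v <- sin(seq(0, 3, length.out = 20))
  g <- make_grid(v, v, seq(20, 90, length.out = 20))
  al <- dtw_align(g, slack = 3)
  expect_equal(al$cost, 0)
  expect_equal(al$path$i, 1:20)
  expect_equal(al$path$j, 1:20)
  sh <- estimate_shift(al, g)
  expect_equal(sh$mean_shift, 0)
  expect_true(all(sh$per_point$shift == 0))
})

test_that("alignment cost equals the exhaustive-path oracle on short grids", {
  set.seed(1)
  for (r in 1:40) {
    n <- sample(4:6, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    for (sl in 0:1) {
      g <- make_grid(a, b, seq(20, 80, length.out = n))
      expect_equal(dtw_align(g, slack = sl)$cost,
                   brute_force_dtw_cost(a, b, sl),
                   tolerance = 1e-12)
    }
  }
})

test_that("mirroring a non-symmetric curve raises the alignment cost", {
  ages <- seq(20, 90, length.out = 30)
  a <- plogis((ages - 40) / 6)          # rising sigmoid
  b <- plogis((ages - 50) / 6)          # same shape, shifted
  g_ok <- make_grid(a, b, ages)
  g_rev <- make_grid(a, rev(b), ages)   # time-reversed reference
  expect_lt(dtw_align(g_ok, slack = 5)$cost,
            dtw_align(g_rev, slack = 5)$cost)
})

test_that("slack validation and grid validation reject bad inputs", {
  g <- make_grid(rnorm(20), rnorm(20))
  expect_error(dtw_align(g, slack = 6), "slack")
  expect_error(dtw_align(g, slack = -1), "slack")
  ages <- seq(20, 90, length.out = 12)
  fit <- fit_best_polynomial(ages, 0.05 * ages + rnorm(12, sd = 0.01))
  expect_error(build_curve_grid(fit, fit, n_grid = 2), "at least 10")
})

test_that("joint standardization preserves a planted age offset on the grid", {
  ages <- seq(20, 95, length.out = 25)
  yB <- 2 + 0.05 * ages
  yA <- 2 + 0.05 * (ages + 10)  # A accelerated by 10 years, same line
  fitA <- fit_best_polynomial(ages, yA)
  fitB <- fit_best_polynomial(ages, yB)
  g <- build_curve_grid(fitA, fitB, n_grid = 50)
  # valuesA at age a equals valuesB at age a + 10 after joint scaling
  approxB <- approx(g$ages, g$valuesB, xout = g$ages + 10)$y
  keep <- !is.na(approxB)
  expect_equal(g$valuesA[keep], approxB[keep], tolerance = 1e-6)
})

test_that("planted onset shifts are recovered with the right sign and size", {
  cfg <- onset_shift_config(n_genes = 12, delta = 10, seed = 13)
  sim <- generate_dataset(cfg)
  ds <- sim$dataset
  agesA <- ds$ages[ds$groups == "A"]
  agesB <- ds$ages[ds$groups == "B"]
  shifts <- vapply(ds$gene_ids, function(g) {
    y <- ds$values[g, ]
    obs <- heterochron:::observed_shifts(agesA, agesB,
                                         y[ds$groups == "A"],
                                         y[ds$groups == "B"])
    (obs$sAB - obs$sBA) / 2
  }, numeric(1))
  expect_gt(min(shifts), 4)
  expect_lt(abs(mean(shifts) - 10), 3)
})

test_that("rate-scale warps yield age-increasing shifts of the planted mean", {
  cfg <- onset_shift_config(n_genes = 8, delta = 10, noise_sd = 0, seed = 17,
                            heterochrony_mode_mix = 0)
  sim <- generate_dataset(cfg)
  ds <- sim$dataset
  agesA <- ds$ages[ds$groups == "A"]
  agesB <- ds$ages[ds$groups == "B"]
  slopes <- vapply(ds$gene_ids, function(g) {
    y <- ds$values[g, ]
    obs <- heterochron:::observed_shifts(agesA, agesB,
                                         y[ds$groups == "A"],
                                         y[ds$groups == "B"],
                                         n_grid = 80, slack = 20)
    pp <- obs$shift$per_point
    unname(coef(lm(pp$shift ~ pp$age))[2])
  }, numeric(1))
  # the planted warp is (k-1)(age - 20): shift grows with age
  expect_gt(median(slopes), 0.05)
})

test_that("swapping the groups negates the mean shift", {
  cfg <- onset_shift_config(n_genes = 6, delta = 8, seed = 19)
  sim <- generate_dataset(cfg)
  ds <- sim$dataset
  step <- (max(ds$ages) - min(ds$ages)) / 49
  for (g in ds$gene_ids[1:4]) {
    y <- ds$values[g, ]
    a <- heterochron:::observed_shifts(
      ds$ages[ds$groups == "A"], ds$ages[ds$groups == "B"],
      y[ds$groups == "A"], y[ds$groups == "B"])
    b <- heterochron:::observed_shifts(
      ds$ages[ds$groups == "B"], ds$ages[ds$groups == "A"],
      y[ds$groups == "B"], y[ds$groups == "A"])
    expect_lt(abs(a$sAB + b$sAB), 2 * step + 1e-9)
  }
})

test_that("null simulation p-values are deterministic and sane", {
  ds <- make_null_dataset(3, seed = 22)
  g <- ds$gene_ids[1]
  p1 <- simulate_null_p(ds, g, observed_stat = 5, n_null = 150, seed = 42)
  p2 <- simulate_null_p(ds, g, observed_stat = 5, n_null = 150, seed = 42)
  expect_identical(p1$p, p2$p)
  # zero observed shift cannot beat any null replicate
  p0 <- simulate_null_p(ds, g, observed_stat = 0, n_null = 150, seed = 42)
  expect_equal(p0$p, 1)
  expect_error(simulate_null_p(ds, g, 1, n_null = 50), "at least 100")
})

test_that("heterochrony test finds a planted shift and respects direction", {
  cfg <- onset_shift_config(n_genes = 6, delta = 10, seed = 23)
  sim <- generate_dataset(cfg)
  res <- heterochrony_test(sim$dataset, "g00001", n_null = 200, seed = 9)
  expect_true(res$significant)
  expect_identical(res$direction, "A-accelerated")
  expect_lt(res$p_A_to_B, 0.05)
  expect_lt(res$p_B_to_A, 0.05)
  expect_lt(abs(res$mean_shift - 10), 4)
  # deterministic under a fixed seed
  res2 <- heterochrony_test(sim$dataset, "g00001", n_null = 200, seed = 9)
  expect_equal(res$p_A_to_B, res2$p_A_to_B)
  expect_equal(res$mean_shift, res2$mean_shift)
})

test_that("nls shift estimator matches exact and degenerate cases", {
  cfg <- onset_shift_config(n_genes = 3, delta = 10, noise_sd = 0, seed = 7)
  sim <- generate_dataset(cfg)
  est <- nls_shift_estimate(sim$dataset, "g00001")
  expect_equal(est$shift, 10, tolerance = 1e-3)

  # A identical to B: shift ~ 0
  ds <- sim$dataset
  vals <- ds$values
  vals[, ds$groups == "A"] <- vals[, ds$groups == "B"]
  ds2 <- expression_dataset(vals, c(ds$ages[ds$groups == "B"],
                                    ds$ages[ds$groups == "B"]),
                            ds$groups)
  expect_lt(abs(nls_shift_estimate(ds2, "g00001")$shift), 0.5)

  # flat reference curve is reported as undefined
  flat <- expression_dataset(matrix(rep(c(1, 1), each = 12), 2, 12,
                                    dimnames = list(c("f1", "f2"), NULL)) +
                               matrix(rnorm(24, sd = 1e-4), 2),
                             runif(12, 20, 90), rep(c("A", "B"), 6))
  res <- nls_shift_estimate(flat, "f1")
  expect_true(is.na(res$shift))
  expect_match(res$reason, "flat")
})
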