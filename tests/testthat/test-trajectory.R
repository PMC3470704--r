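test_that("exact signals select the right polynomial degree", {
  ages <- c(25, 31, 40, 47, 55, 63, 70, 78, 85, 93)
  # exactly linear: degree 1, perfect fit
  fit <- fit_best_polynomial(ages, 2 + 0.05 * ages)
  expect_identical(fit$degree, 1L)
  expect_equal(fit$adjusted_r2, 1)
  expect_lt(fit$rss, 1e-20)
  # constant: degree 0
  expect_identical(fit_best_polynomial(ages, rep(3, 10))$degree, 0L)
  # selected adjusted r2 dominates every other degree tried
  set.seed(1)
  for (r in 1:20) {
    y <- rnorm(10)
    f <- fit_best_polynomial(ages, y)
    adj <- 1 - (f$rss_by_degree / f$tss) * (9 / (10 - 0:3 - 1))
    adj[1] <- 0
    expect_gte(f$adjusted_r2 + 1e-10, max(adj))
  }
})

test_that("high-SNR quadratic signals are never underfit", {
  set.seed(2)
  ages <- c(runif(20, 20, 99), runif(20, 20, 99))
  sel <- integer(200)
  for (r in 1:200) {
    co <- heterochron:::random_trajectory(2, 20, 99, 1, 8)
    y <- heterochron:::eval_poly(co, ages, 59.5) + rnorm(40, sd = 0.02)
    sel[r] <- fit_best_polynomial(ages, y)$degree
  }
  # curvature is always captured; adjusted r2 occasionally admits a
  # superfluous cubic term, but degree 2 remains the modal choice
  expect_gte(mean(sel >= 2), 0.95)
  expect_gt(mean(sel == 2), 0.5)
})

test_that("age test: calibration, power and invariances", {
  set.seed(3)
  ages <- c(runif(20, 20, 99), runif(20, 20, 99))
  # null calibration: adaptive degree selection makes the F-test mildly
  # anticonservative (measured ~0.085 at alpha 0.05)
  p0 <- replicate(1000, age_test(ages, rnorm(40))$p)
  expect_gte(mean(p0 < 0.05), 0.03)
  expect_lte(mean(p0 < 0.05), 0.10)
  # strong linear signal
  y <- 0.05 * ages + rnorm(40, sd = 0.1)
  expect_lt(age_test(ages, y)$p, 1e-6)
  # constant values give p = 1
  expect_equal(age_test(ages, rep(2, 40))$p, 1)
  # invariance under shifting all values or all ages
  set.seed(4)
  y2 <- 0.02 * ages + rnorm(40, sd = 0.3)
  expect_equal(age_test(ages, y2)$p, age_test(ages, y2 + 100)$p)
  expect_equal(age_test(ages, y2)$p, age_test(ages + 50, y2)$p)
})

test_that("ANCOVA divergence test: F formula, symmetry, trivial cases", {
  set.seed(5)
  n <- 15
  ages <- c(runif(n, 20, 99), runif(n, 20, 99))
  groups <- rep(c("A", "B"), each = n)
  y <- 0.03 * ages + rnorm(2 * n, sd = 0.3) + ifelse(groups == "A", 1, 0)

  res <- ancova_divergence_test(ages, y, groups)
  # direct RSS-formula recomputation at the selected degree
  d <- res$degree
  X <- outer(ages - mean(ages), 0:d, `^`)
  rss_p <- sum(lm.fit(X, y)$residuals^2)
  rss_f <- sum(lm.fit(X[groups == "A", , drop = FALSE],
                      y[groups == "A"])$residuals^2) +
           sum(lm.fit(X[groups == "B", , drop = FALSE],
                      y[groups == "B"])$residuals^2)
  Fref <- ((rss_p - rss_f) / (d + 1)) / (rss_f / (2 * n - 2 * (d + 1)))
  expect_equal(res$F, Fref, tolerance = 1e-12)
  expect_lt(res$p, 1e-4)

  # invariant under swapping the group labels
  expect_equal(res$p, ancova_divergence_test(
    ages, y, ifelse(groups == "A", "B", "A"))$p)

  # identical data in both groups: F ~ 0, p ~ 1
  yA <- 0.04 * ages[1:n] + rnorm(n, sd = 0.2)
  res0 <- ancova_divergence_test(c(ages[1:n], ages[1:n]), c(yA, yA), groups)
  expect_lt(res0$F, 1e-8)
  expect_gt(res0$p, 0.999)

  # strong offset
  y3 <- 0.03 * ages + rnorm(2 * n, sd = 0.1) + ifelse(groups == "A", 5, 0)
  expect_lt(ancova_divergence_test(ages, y3, groups)$p, 1e-6)

  # insufficient group size names the group
  expect_error(
    ancova_divergence_test(ages[1:4], rnorm(4), c("A", "A", "A", "B")),
    "B")
})

test_that("co-direction test behaves on identical, negated and flat fits", {
  ages <- seq(20, 90, length.out = 25)
  fitA <- fit_best_polynomial(ages, 1 + 0.05 * ages +
                                rep_len(c(0.01, -0.01), length(ages)))
  grid <- seq(25, 85, length.out = 40)
  same <- codirection_test(fitA, fitA, grid)
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_true(same$pass)

  neg <- fitA
  neg$coefficients <- -neg$coefficients
  opp <- codirection_test(fitA, neg, grid)
  expect_equal(opp$r, -1, tolerance = 1e-12)
  expect_false(opp$pass)

  flat <- fit_best_polynomial(ages, rep(2, 25))
  res <- codirection_test(fitA, flat, grid)
  expect_false(res$pass)
  expect_match(res$reason, "flat|zero-variance")

  expect_error(codirection_test(fitA, fitA, 1:5), "20 points")
})

test_that("cascade recovers planted age-related genes and nests in alpha", {
  cfg <- simulation_config(n_genes = 300, n_per_group = 20, noise_sd = 0.25,
                           signal_amplitude = 1, frac_age_related = 0.5,
                           seed = 21)
  sim <- generate_dataset(cfg)
  casc <- run_cascade(sim$dataset)
  tr <- sim$truth
  # sensitivity at signal-to-noise 4
  expect_gte(mean(casc$passes_stage1[tr$is_age_related]), 0.9)
  # stages nest
  expect_true(all(casc$passes_stage2 <= casc$passes_stage1))
  expect_true(all(casc$passes_stage3 <= casc$passes_stage2))
  # survivor sets nest as alpha grows
  casc_loose <- run_cascade(sim$dataset, alpha = 0.2)
  expect_true(all(eligible_genes(casc) %in% eligible_genes(casc_loose)))
  # alpha = 0 passes nothing
  expect_length(eligible_genes(run_cascade(sim$dataset, alpha = 0)), 0)
})

test_that("null dataset passes stage 1 at roughly the nominal rate", {
  ds <- make_null_dataset(400, seed = 8)
  # genes have real age trajectories shared by the groups: stage 1 fires,
  # stage 2 (divergence) should be near alpha
  casc <- run_cascade(ds)
  div_rate <- mean(casc$divergence_p < 0.05, na.rm = TRUE)
  expect_gte(div_rate, 0.02)
  expect_lte(div_rate, 0.09)
})
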