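# Independent oracles and small dataset builders shared across test files.

# Exhaustive-enumeration DTW oracle: minimum cost over all admissible
# monotone paths with open ends within `slack` of the corners. Recursive
# branch-and-bound; only feasible for short grids.
brute_force_dtw_cost <- function(a, b, slack) {
  n <- length(a)
  m <- length(b)
  best <- Inf
  rec <- function(i, j, cost) {
    cost <- cost + (a[i] - b[j])^2
    if (cost >= best) return(invisible())
    if ((i == n && m - j <= slack) || (j == m && n - i <= slack))
      best <<- min(best, cost)
    if (i < n && j < m) rec(i + 1, j + 1, cost)
    if (i < n) rec(i + 1, j, cost)
    if (j < m) rec(i, j + 1, cost)
  }
  starts <- unique(rbind(cbind(seq_len(slack + 1), 1),
                         cbind(1, seq_len(slack + 1))))
  for (k in seq_len(nrow(starts))) rec(starts[k, 1], starts[k, 2], 0)
  best
}

# Curve grid wrapper for raw value vectors on an age grid.
make_grid <- function(a, b, ages = seq(20, 90, length.out = length(a))) {
  structure(list(ages = ages, valuesA = a, valuesB = b),
            class = "curve_grid")
}

# Exhaustive hypergeometric upper tail: P(overlap >= k) summed from the
# closed-form counting formula, independent of stats::phyper.
enum_hyper_tail <- function(k, sizeA, sizeB, N) {
  ks <- k:min(sizeA, sizeB)
  sum(choose(sizeA, ks) * choose(N - sizeA, sizeB - ks)) / choose(N, sizeB)
}

# A dataset in which every gene shares one trajectory between groups
# (the global null for divergence/heterochrony), built outside the
# package generator so calibration tests do not lean on it.
make_null_dataset <- function(n_genes, n_per_group = 20, noise_sd = 0.25,
                              seed = 1) {
  set.seed(seed)
  agesA <- sort(runif(n_per_group, 20, 99))
  agesB <- sort(runif(n_per_group, 20, 99))
  ages <- c(agesA, agesB)
  vals <- matrix(NA_real_, n_genes, 2 * n_per_group)
  for (g in seq_len(n_genes)) {
    degree <- sample(1:3, 1)
    coef <- c(0, rnorm(degree) / 40^seq_len(degree))
    f <- heterochron:::eval_poly(coef, ages, 59.5)
    f <- (f - mean(f)) / max(sd(f), 1e-9)
    vals[g, ] <- 8 + f + rnorm(2 * n_per_group, sd = noise_sd)
  }
  expression_dataset(vals, ages, rep(c("A", "B"), each = n_per_group))
}

# Standard planted onset-shift configuration: every gene age-related,
# divergent, heterochronic in group A's direction, delta years, linear
# trajectories, signal-to-noise = amplitude / noise.
onset_shift_config <- function(n_genes, delta = 10, noise_sd = 0.25,
                               seed = 11, ...) {
  args <- list(n_genes = n_genes, n_per_group = 20,
               signal_amplitude = 1, noise_sd = noise_sd,
               frac_age_related = 1,
               frac_divergent_given_age_related = 1,
               frac_heterochronic_given_divergent = 1,
               direction_bias = 1, heterochrony_mode_mix = 1,
               shift_years = delta,
               trajectory_degree_weights = c(0, 1, 0, 0),
               seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
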