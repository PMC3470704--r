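#' Build a shared curve grid for two fitted trajectories
#'
#' Evaluates both groups' fitted polynomial curves on an equally-spaced grid
#' spanning the overlap of the two groups' observed age ranges, then jointly
#' standardizes the two curves (one shared mean and SD across both, sample-SD
#' denominator). Joint standardization preserves the vertical offset between
#' the curves relative to their common scale, so a pure offset between
#' monotone curves is not mistaken for a maximal time shift, while shape
#' still dominates the alignment; set `joint_standardize = FALSE` to align
#' raw fitted values.
#'
#' @param fitA,fitB `poly_fit` objects for the two groups (see
#'   [fit_best_polynomial()]).
#' @param n_grid number of grid points (minimum 10, default 50).
#' @param joint_standardize standardize the two curves with a shared
#'   mean/SD (default TRUE).
#' @return A `curve_grid` object: `ages`, `valuesA`, `valuesB`.
#' @export
build_curve_grid <- function(fitA, fitB, n_grid = 50, joint_standardize = TRUE) {
  if (n_grid < 10L) stop("n_grid must be at least 10")
  lo <- max(fitA$age_range[1], fitB$age_range[1])
  hi <- min(fitA$age_range[2], fitB$age_range[2])
  if (lo >= hi) stop("the two fits' age ranges do not overlap")
  ages <- seq(lo, hi, length.out = n_grid)
  vA <- predict(fitA, ages)
  vB <- predict(fitB, ages)
  if (joint_standardize) {
    both <- c(vA, vB)
    mu <- mean(both)
    s <- stats::sd(both)
    if (s < 1e-12) s <- 1
    vA <- (vA - mu) / s
    vB <- (vB - mu) / s
  }
  structure(list(ages = ages, valuesA = vA, valuesB = vB),
            class = "curve_grid")
}

#' Open-ended dynamic time warping alignment of two curves
#'
#' Finds the minimum-cost monotone warping path between the query and
#' reference curves under squared-difference local cost with step set
#' \{(1,0),(0,1),(1,1)\}. End matching is relaxed: the path may start at
#' `(i,1)` or `(1,j)` and end at `(n,j)` or `(i,n)` within `slack` grid
#' points of the corners, so partially overlapping (time-shifted)
#' trajectories can align without forcing their ends together.
#' Deterministic tie-breaks prefer the diagonal step, then advancing the
#' query index.
#'
#' @param grid a `curve_grid` from [build_curve_grid()].
#' @param slack open-end slack in grid points, `0 <= slack <= n_grid/4`
#'   (default 5).
#' @param direction `"AtoB"` (A is the query, default) or `"BtoA"`.
#' @return An `alignment_path` object: data frame `path` with 1-based
#'   indices `i` (query) and `j` (reference), `cost` (cumulative squared
#'   difference), `direction`, `slack`.
#' @export
dtw_align <- function(grid, slack = 5, direction = c("AtoB", "BtoA")) {
  stopifnot(inherits(grid, "curve_grid"))
  direction <- match.arg(direction)
  n <- length(grid$ages)
  if (slack < 0 || slack > ceiling(n / 4))
    stop("slack must lie in [0, ceiling(n_grid/4)] = [0, ", ceiling(n / 4), "]")
  q <- if (direction == "AtoB") grid$valuesA else grid$valuesB
  r <- if (direction == "AtoB") grid$valuesB else grid$valuesA
  res <- dtw_align_cpp(q, r, as.integer(slack))
  structure(list(path = data.frame(i = res$i, j = res$j),
                 cost = res$cost, direction = direction, slack = slack),
            class = "alignment_path")
}

#' Estimate per-time-point and mean shifts from an alignment path
#'
#' For each query grid point on the path, the shift is the mean of
#' (reference age - query age) over its matched reference points; the mean
#' shift averages these per-point shifts. A positive mean shift means the
#' query group's trajectory corresponds to the reference group's older ages,
#' i.e. the query group is accelerated.
#'
#' @param path an `alignment_path` from [dtw_align()].
#' @param grid the `curve_grid` the path was computed on.
#' @return A `shift_estimate` object: `per_point` (data frame `i`, `age`,
#'   `shift`), `mean_shift` (years), `direction` (`"none"` until a
#'   significance call is made).
#' @export
estimate_shift <- function(path, grid) {
  stopifnot(inherits(path, "alignment_path"), inherits(grid, "curve_grid"))
  p <- path$path
  if (nrow(p) == 0L) stop("empty alignment path")
  ages <- grid$ages
  per <- vapply(split(ages[p$j], p$i),
                function(a) mean(a), numeric(1))
  qi <- as.integer(names(per))
  shifts <- per - ages[qi]
  structure(list(per_point = data.frame(i = qi, age = ages[qi],
                                        shift = unname(shifts)),
                 mean_shift = mean(shifts),
                 direction = "none"),
            class = "shift_estimate")
}

# ---- internal batch machinery ------------------------------------------

# Fit degrees 0..max_degree to every column of Y (samples x replicates) by
# adjusted R-squared (strict improvement > 1e-10, matching
# fit_best_polynomial), and evaluate each replicate's selected curve on
# `grid`. Returns list(curves = grid x replicates, degree).
batch_fit_curves <- function(ages, Y, grid, max_degree = 3) {
  n <- length(ages)
  R <- ncol(Y)
  ctr <- mean(ages)
  u <- ages - ctr
  ug <- grid - ctr
  X <- outer(u, 0:max_degree, `^`)
  G <- outer(ug, 0:max_degree, `^`)
  mu <- colMeans(Y)
  tss <- colSums(Y^2) - n * mu^2
  best_adj <- rep(0, R)
  best_deg <- rep(0L, R)
  curves <- matrix(mu, length(grid), R, byrow = TRUE)
  for (d in seq_len(min(max_degree, n - 2L))) {
    qrX <- qr(X[, 1:(d + 1), drop = FALSE])
    cf <- qr.coef(qrX, Y)
    fitted <- X[, 1:(d + 1), drop = FALSE] %*% cf
    rss <- colSums((Y - fitted)^2)
    adj <- 1 - (rss / tss) * (n - 1) / (n - d - 1)
    adj[!is.finite(adj)] <- -Inf
    better <- adj > best_adj + 1e-10
    if (any(better)) {
      best_deg[better] <- d
      best_adj[better] <- adj[better]
      curves[, better] <- G[, 1:(d + 1), drop = FALSE] %*%
        cf[, better, drop = FALSE]
    }
  }
  list(curves = curves, degree = best_deg)
}

# Jointly standardize paired curve matrices (columns are replicates) with a
# shared per-replicate mean/SD, mirroring build_curve_grid.
joint_standardize_pairs <- function(CA, CB) {
  g2 <- nrow(CA) + nrow(CB)
  mu <- (colSums(CA) + colSums(CB)) / g2
  ss <- colSums(sweep(CA, 2, mu)^2) + colSums(sweep(CB, 2, mu)^2)
  s <- sqrt(ss / (g2 - 1))
  s[s < 1e-12] <- 1
  list(A = sweep(sweep(CA, 2, mu), 2, s, "/"),
       B = sweep(sweep(CB, 2, mu), 2, s, "/"))
}

# Parametric-bootstrap null: both groups share the pooled curve; Gaussian
# noise with the pooled residual SD is added at the real samples' ages.
# Returns an n_null x 2 matrix of null mean shifts (columns: A->B, B->A),
# or NULL when the pooled fit is degenerate.
null_shift_batch <- function(agesA, agesB, valsA, valsB, n_null,
                             n_grid = 50, slack = 5, max_degree = 3) {
  ages <- c(agesA, agesB)
  pooled <- fit_best_polynomial(ages, c(valsA, valsB), max_degree)
  df <- pooled$n - pooled$degree - 1
  sigma <- sqrt(pooled$rss / df)
  if (!is.finite(sigma) || sigma < 1e-12) return(NULL)
  lo <- max(min(agesA), min(agesB))
  hi <- min(max(agesA), max(agesB))
  grid <- seq(lo, hi, length.out = n_grid)
  muA <- predict(pooled, agesA)
  muB <- predict(pooled, agesB)
  YA <- matrix(stats::rnorm(length(agesA) * n_null, mean = muA, sd = sigma),
               length(agesA), n_null)
  YB <- matrix(stats::rnorm(length(agesB) * n_null, mean = muB, sd = sigma),
               length(agesB), n_null)
  fA <- batch_fit_curves(agesA, YA, grid, max_degree)
  fB <- batch_fit_curves(agesB, YB, grid, max_degree)
  std <- joint_standardize_pairs(fA$curves, fB$curves)
  dtw_shift_batch(std$A, std$B, grid, as.integer(slack))
}

# Observed bidirectional mean shifts for one gene. Returns list(sAB, sBA,
# shift (the A->B shift_estimate), fitA, fitB, grid).
observed_shifts <- function(agesA, agesB, valsA, valsB,
                            n_grid = 50, slack = 5, max_degree = 3) {
  fitA <- fit_best_polynomial(agesA, valsA, max_degree)
  fitB <- fit_best_polynomial(agesB, valsB, max_degree)
  grid <- build_curve_grid(fitA, fitB, n_grid)
  pAB <- dtw_align(grid, slack, "AtoB")
  pBA <- dtw_align(grid, slack, "BtoA")
  sAB <- estimate_shift(pAB, grid)
  # for B->A the query is B, so reference ages are A's
  pb <- pBA$path
  perB <- vapply(split(grid$ages[pb$j], pb$i), mean, numeric(1))
  qiB <- as.integer(names(perB))
  sBA_mean <- mean(perB - grid$ages[qiB])
  list(sAB = sAB$mean_shift, sBA = sBA_mean, shift = sAB,
       fitA = fitA, fitB = fitB, grid = grid)
}

gene_values <- function(ds, gene) {
  row <- match(gene, ds$gene_ids)
  if (is.na(row)) stop("unknown gene: ", gene)
  ds$values[row, ]
}

# ---- user-facing significance machinery --------------------------------

#' Simulation-based p-value for an observed time shift
#'
#' Null model: the two groups share one trajectory. The pooled curve is fit
#' across both groups, its residual SD estimated, and `n_null` synthetic
#' gene datasets are generated by adding Gaussian noise to the pooled curve
#' at the real samples' ages. Each replicate is pushed through the full
#' fit -> grid -> align -> shift pipeline and the p-value is the add-one
#' estimator `p = (1 + #{|null shift| >= |observed|}) / (n_null + 1)`, so
#' p is never exactly zero.
#'
#' @param ds an [expression_dataset()].
#' @param gene gene id.
#' @param observed_stat observed mean shift in years (its absolute value is
#'   the test statistic).
#' @param n_null number of null replicates (minimum 100).
#' @param seed optional integer seed for the null draws.
#' @param direction `"AtoB"` or `"BtoA"`: which alignment the statistic came
#'   from.
#' @param n_grid,slack,max_degree pipeline parameters, see [dtw_align()].
#' @return List: `p`, `n_null`, `null_shifts` (the null statistics for the
#'   requested direction), `reason` (non-empty when the pooled fit is
#'   degenerate and p = 1 is returned).
#' @export
simulate_null_p <- function(ds, gene, observed_stat, n_null = 1000,
                            seed = NULL, direction = c("AtoB", "BtoA"),
                            n_grid = 50, slack = 5, max_degree = 3) {
  stopifnot(inherits(ds, "expression_dataset"))
  direction <- match.arg(direction)
  if (n_null < 100) stop("n_null must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  y <- gene_values(ds, gene)
  gA <- group_slice(ds, 1)
  gB <- group_slice(ds, 2)
  yA <- y[ds$groups == gA$level]
  yB <- y[ds$groups == gB$level]
  nulls <- null_shift_batch(gA$ages, gB$ages, yA, yB, n_null,
                            n_grid, slack, max_degree)
  if (is.null(nulls))
    return(list(p = 1, n_null = n_null, null_shifts = numeric(0),
                reason = "degenerate pooled fit (zero residual variance)"))
  stat <- nulls[, if (direction == "AtoB") 1 else 2]
  p <- (1 + sum(abs(stat) >= abs(observed_stat))) / (n_null + 1)
  list(p = p, n_null = n_null, null_shifts = stat, reason = "")
}

#' Bidirectional heterochrony test for one gene
#'
#' Aligns group A's fitted trajectory to group B's and vice versa, estimates
#' the mean time shift for each direction, and assesses each against the
#' simulation null (one set of `n_null` pooled-curve replicates scores both
#' directions). A gene is significantly heterochronic only when both
#' directional p-values fall below `alpha` and the two directions agree on
#' which group is accelerated; the direction is then read from the sign of
#' the A-to-B mean shift (positive = group A accelerated).
#'
#' @param ds an [expression_dataset()].
#' @param gene gene id (should have passed [run_cascade()]).
#' @param alpha significance level (default 0.05).
#' @param n_null null replicates (minimum 100).
#' @param seed optional integer seed.
#' @param n_grid,slack,max_degree pipeline parameters.
#' @param null_mode `"parametric"` (default; pooled-curve Gaussian
#'   replicates) or `"permutation"` (group labels permuted, preserving the
#'   pooled age design only on average).
#' @return A `heterochrony_result`: `gene`, `p_A_to_B`, `p_B_to_A`,
#'   `significant`, `direction` (`"A-accelerated"`, `"B-accelerated"` or
#'   `"none"`), `mean_shift` (years, positive = A accelerated, averaged over
#'   the two directions), `shift` (the A-to-B `shift_estimate` with
#'   per-grid-point shifts), `n_null`, `seed`, `reason`.
#' @export
heterochrony_test <- function(ds, gene, alpha = 0.05, n_null = 1000,
                              seed = NULL, n_grid = 50, slack = 5,
                              max_degree = 3,
                              null_mode = c("parametric", "permutation")) {
  stopifnot(inherits(ds, "expression_dataset"))
  null_mode <- match.arg(null_mode)
  if (n_null < 100) stop("n_null must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  y <- gene_values(ds, gene)
  gA <- group_slice(ds, 1)
  gB <- group_slice(ds, 2)
  yA <- y[ds$groups == gA$level]
  yB <- y[ds$groups == gB$level]

  obs <- observed_shifts(gA$ages, gB$ages, yA, yB, n_grid, slack, max_degree)
  nulls <- if (null_mode == "parametric")
    null_shift_batch(gA$ages, gB$ages, yA, yB, n_null,
                     n_grid, slack, max_degree)
  else
    permutation_shift_null(gA$ages, gB$ages, yA, yB, n_null,
                           n_grid, slack, max_degree)
  if (is.null(nulls)) {
    return(structure(list(gene = gene, p_A_to_B = 1, p_B_to_A = 1,
                          significant = FALSE, direction = "none",
                          mean_shift = obs$shift$mean_shift,
                          shift = obs$shift, n_null = n_null, seed = seed,
                          reason = "degenerate pooled fit"),
                     class = "heterochrony_result"))
  }
  pAB <- (1 + sum(abs(nulls[, 1]) >= abs(obs$sAB))) / (n_null + 1)
  pBA <- (1 + sum(abs(nulls[, 2]) >= abs(obs$sBA))) / (n_null + 1)
  # the two directions must implicate the same accelerated group: the B->A
  # shift has opposite sign to the A->B shift when they agree
  agree <- sign(obs$sAB) != 0 && sign(obs$sAB) == -sign(obs$sBA)
  significant <- pAB < alpha && pBA < alpha && agree
  direction <- if (!significant) "none"
  else if (obs$sAB > 0) "A-accelerated" else "B-accelerated"
  shift <- obs$shift
  shift$direction <- direction
  reason <- if (pAB < alpha && pBA < alpha && !agree)
    "directional shifts disagree in sign" else ""
  structure(list(gene = gene, p_A_to_B = pAB, p_B_to_A = pBA,
                 significant = significant, direction = direction,
                 mean_shift = (obs$sAB - obs$sBA) / 2,
                 shift = shift, n_null = n_null, seed = seed,
                 reason = reason),
            class = "heterochrony_result")
}

#' @export
print.heterochrony_result <- function(x, ...) {
  cat(sprintf(paste0("heterochrony_result for %s: p(A->B) = %.4g, ",
                     "p(B->A) = %.4g\n  mean shift = %.2f years, %s%s\n"),
              x$gene, x$p_A_to_B, x$p_B_to_A, x$mean_shift,
              if (x$significant) "significant: " else "not significant",
              if (x$significant) x$direction else ""))
  invisible(x)
}

# Label-permutation null (optional alternative to the parametric null).
permutation_shift_null <- function(agesA, agesB, valsA, valsB, n_null,
                                   n_grid, slack, max_degree) {
  ages <- c(agesA, agesB)
  vals <- c(valsA, valsB)
  nA <- length(agesA)
  out <- matrix(NA_real_, n_null, 2)
  for (r in seq_len(n_null)) {
    idx <- sample.int(length(ages), nA)
    aA <- ages[idx]; vA <- vals[idx]
    aB <- ages[-idx]; vB <- vals[-idx]
    res <- tryCatch(
      observed_shifts(aA, aB, vA, vB, n_grid, slack, max_degree),
      error = function(e) NULL)
    if (!is.null(res)) out[r, ] <- c(res$sAB, res$sBA)
  }
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (nrow(out) == 0L) NULL else out
}

#' Nonlinear-least-squares time-shift estimator
#'
#' The alternative to the warping estimator: finds the shift `delta`
#' minimizing the mean squared difference between group A's observed
#' values and group B's fitted curve evaluated at (age + delta), by 1-D
#' minimization over `delta` in [-span/2, +span/2] (span = group B's
#' observed age span). Only A samples whose shifted age falls inside group
#' B's observed age range enter the objective (at least half must remain),
#' so the fitted polynomial is never evaluated outside its data support --
#' the analogue of the warping test's relaxed end matching, and essential
#' because extrapolated cubics are unbounded. A coarse half-year grid
#' search brackets the optimum before [stats::optimize()] refines it,
#' guarding against local minima of higher-degree curves. Positive
#' estimates mean group A is accelerated.
#'
#' @param ds an [expression_dataset()].
#' @param gene gene id.
#' @param max_degree maximum polynomial degree for the group-B fit.
#' @return List: `shift` (years; `NA` with a `reason` when group B's curve
#'   is flat), `objective` (residual sum of squares at the optimum),
#'   `fitB`.
#' @export
nls_shift_estimate <- function(ds, gene, max_degree = 3) {
  stopifnot(inherits(ds, "expression_dataset"))
  y <- gene_values(ds, gene)
  gA <- group_slice(ds, 1)
  gB <- group_slice(ds, 2)
  yA <- y[ds$groups == gA$level]
  yB <- y[ds$groups == gB$level]
  fitB <- fit_best_polynomial(gB$ages, yB, max_degree)
  if (fitB$degree == 0L)
    return(list(shift = NA_real_, objective = NA_real_, fitB = fitB,
                reason = "flat group-B curve: shift undefined"))
  span <- diff(fitB$age_range)
  obj <- function(delta) {
    shifted <- gA$ages + delta
    keep <- shifted >= fitB$age_range[1] & shifted <= fitB$age_range[2]
    if (sum(keep) < length(shifted) / 2) return(Inf)
    mean((yA[keep] - predict(fitB, shifted[keep]))^2)
  }
  cand <- seq(-span / 2, span / 2, by = 0.5)
  vals <- vapply(cand, obj, numeric(1))
  k <- which.min(vals)
  lo <- cand[max(1, k - 1)]
  hi <- cand[min(length(cand), k + 1)]
  opt <- stats::optimize(obj, c(lo, hi))
  list(shift = opt$minimum, objective = opt$objective, fitB = fitB,
       reason = "")
}
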