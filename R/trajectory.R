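#' Fit the best polynomial age trajectory by adjusted R-squared
#'
#' Fits ordinary least squares polynomials of degree 0 through `max_degree`
#' in centered age (age minus mean age, for numerical conditioning) and
#' returns the fit maximizing adjusted R-squared; ties within 1e-10 go to
#' the lower degree. The feasible degree is capped at `n - 2` and at the
#' number of distinct ages minus one (with a warning) so the design is never
#' rank-deficient.
#'
#' @param ages numeric ages in years.
#' @param values numeric expression values, same length.
#' @param max_degree maximum polynomial degree (default 3).
#' @return A `poly_fit` object: `degree`, `coefficients` (centered basis,
#'   intercept first), `adjusted_r2`, `rss`, `tss`, `n`, `center`,
#'   `age_range`, `rss_by_degree`.
#' @export
fit_best_polynomial <- function(ages, values, max_degree = 3) {
  n <- length(ages)
  if (length(values) != n) stop("ages and values must have equal length")
  if (n < max_degree + 2)
    stop("need at least max_degree + 2 = ", max_degree + 2, " samples, got ", n)
  if (length(unique(ages)) < 2L) stop("ages must not all be identical")
  feas <- min(max_degree, length(unique(ages)) - 1L, n - 2L)
  if (feas < max_degree)
    warning("degree capped at ", feas, " (insufficient samples or distinct ages)")

  center <- mean(ages)
  u <- ages - center
  X <- outer(u, 0:feas, `^`)
  ybar <- mean(values)
  tss <- sum((values - ybar)^2)

  rss_by_degree <- numeric(feas + 1)
  coefs <- vector("list", feas + 1)
  rss_by_degree[1] <- tss
  coefs[[1]] <- ybar
  for (d in seq_len(feas)) {
    fit <- stats::lm.fit(X[, 1:(d + 1), drop = FALSE], values)
    coefs[[d + 1]] <- fit$coefficients
    rss_by_degree[d + 1] <- sum(fit$residuals^2)
  }
  adj <- if (tss < 1e-300) rep(0, feas + 1) else {
    r2 <- 1 - rss_by_degree / tss
    1 - (1 - r2) * (n - 1) / (n - (0:feas) - 1)
  }
  best <- 1L
  for (d in seq_len(feas))
    if (adj[d + 1] > adj[best] + 1e-10) best <- d + 1L

  structure(list(degree = best - 1L,
                 coefficients = unname(coefs[[best]]),
                 adjusted_r2 = adj[best],
                 rss = rss_by_degree[best],
                 tss = tss,
                 n = n,
                 center = center,
                 age_range = range(ages),
                 rss_by_degree = rss_by_degree),
            class = "poly_fit")
}

#' Evaluate a fitted polynomial trajectory at new ages
#' @param object a `poly_fit` from [fit_best_polynomial()].
#' @param newages ages (years) to evaluate at.
#' @param ... unused.
#' @export
predict.poly_fit <- function(object, newages, ...) {
  eval_poly(object$coefficients, newages, object$center)
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("poly_fit: degree %d, adj r2 = %.4f, rss = %.4g, n = %d\n",
              x$degree, x$adjusted_r2, x$rss, x$n))
  invisible(x)
}

#' Test for an age effect on expression
#'
#' Selects the polynomial degree by adjusted R-squared, then F-tests the
#' selected model against the intercept-only model:
#' `F = ((RSS0 - RSS1)/d) / (RSS1/(n - d - 1))` with `d` the selected
#' degree. Selection of degree 0 (no trajectory beats the intercept) yields
#' p = 1.
#'
#' @inheritParams fit_best_polynomial
#' @return List: `p`, `F`, `fit` (the selected `poly_fit`).
#' @export
age_test <- function(ages, values, max_degree = 3) {
  fit <- fit_best_polynomial(ages, values, max_degree)
  d <- fit$degree
  if (d == 0L || fit$tss < 1e-300)
    return(list(p = 1, F = 0, fit = fit))
  rss0 <- fit$tss
  rss1 <- fit$rss
  df2 <- fit$n - d - 1
  Fstat <- if (rss1 < 1e-300) Inf else ((rss0 - rss1) / d) / (rss1 / df2)
  list(p = stats::pf(Fstat, d, df2, lower.tail = FALSE), F = Fstat, fit = fit)
}

#' ANCOVA-style trajectory divergence test between two groups
#'
#' Compares one pooled age curve for all samples against independent
#' per-group curves of the same degree. The degree is chosen once, on the
#' pooled data, by adjusted R-squared, so the models are nested and the
#' F-test is valid: `F = ((RSS_pooled - RSS_full)/(d+1)) /
#' (RSS_full/(n - 2(d+1)))` with `d+1` numerator degrees of freedom.
#'
#' @param ages,values numeric vectors over all samples.
#' @param groups two-level factor (or coercible) per sample.
#' @param max_degree maximum polynomial degree for the pooled selection.
#' @return List: `p`, `F`, `degree`, `rss_pooled`, `rss_full`, per-group
#'   fits `fitA`, `fitB` (at the pooled degree, centered on the pooled mean
#'   age).
#' @export
ancova_divergence_test <- function(ages, values, groups, max_degree = 3) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  n <- length(ages)
  ng <- table(groups)
  feas <- min(max_degree, min(ng) - 2L)
  if (feas < 0)
    stop("insufficient samples in group ", names(ng)[which.min(ng)],
         " (need >= 2)")
  pooled <- fit_best_polynomial(ages, values, max_degree = feas)
  d <- pooled$degree
  # full model: independent curves per group at the pooled degree; guard the
  # denominator df
  if (n - 2 * (d + 1) < 1) d <- max(0L, floor((n - 1) / 2) - 1L)
  center <- mean(ages)
  u <- ages - center
  rss_full <- 0
  gfits <- list()
  for (lev in levels(groups)) {
    sel <- groups == lev
    Xg <- outer(u[sel], 0:d, `^`)
    fit <- stats::lm.fit(Xg, values[sel])
    rss_full <- rss_full + sum(fit$residuals^2)
    gfits[[lev]] <- structure(
      list(degree = d, coefficients = unname(fit$coefficients),
           adjusted_r2 = NA_real_, rss = sum(fit$residuals^2),
           tss = sum((values[sel] - mean(values[sel]))^2),
           n = sum(sel), center = center, age_range = range(ages[sel]),
           rss_by_degree = NULL),
      class = "poly_fit")
  }
  rss_pooled <- if (d == pooled$degree) pooled$rss else {
    fit <- stats::lm.fit(outer(u, 0:d, `^`), values)
    sum(fit$residuals^2)
  }
  df1 <- d + 1
  df2 <- n - 2 * (d + 1)
  Fstat <- if (rss_full < 1e-300) {
    if (rss_pooled - rss_full < 1e-300) 0 else Inf
  } else ((rss_pooled - rss_full) / df1) / (rss_full / df2)
  Fstat <- max(Fstat, 0)
  list(p = stats::pf(Fstat, df1, df2, lower.tail = FALSE), F = Fstat,
       degree = d, rss_pooled = rss_pooled, rss_full = rss_full,
       fitA = gfits[[1]], fitB = gfits[[2]])
}

#' Co-direction test between two fitted trajectories
#'
#' Pearson correlation between the two groups' fitted curves evaluated on a
#' shared age grid, with a one-sided p-value for positive correlation. A
#' divergence that passes this filter can be explained by a time shift; an
#' anti-correlated pair (opposite trends) cannot.
#'
#' @param fitA,fitB `poly_fit` objects for the two groups.
#' @param age_grid numeric grid of at least 20 ages inside both fits'
#'   observed ranges.
#' @return List: `r`, `p` (one-sided, r > 0), `pass`, `reason`.
#' @export
codirection_test <- function(fitA, fitB, age_grid) {
  if (length(age_grid) < 20L) stop("age_grid needs at least 20 points")
  if (fitA$degree == 0L || fitB$degree == 0L)
    return(list(r = NA_real_, p = NA_real_, pass = FALSE,
                reason = "flat trajectory: correlation undefined"))
  cA <- predict(fitA, age_grid)
  cB <- predict(fitB, age_grid)
  if (stats::sd(cA) < 1e-12 || stats::sd(cB) < 1e-12)
    return(list(r = NA_real_, p = NA_real_, pass = FALSE,
                reason = "zero-variance curve"))
  ct <- stats::cor.test(cA, cB, alternative = "greater")
  list(r = unname(ct$estimate), p = ct$p.value,
       pass = ct$p.value < 0.05, reason = "")
}

#' Run the per-gene heterochrony eligibility cascade
#'
#' Applies, per gene and in order: (1) the polynomial age-effect test on all
#' samples, (2) the ANCOVA divergence test between groups, (3) the
#' co-direction filter on the per-group fitted curves. Each stage uses the
#' raw p-value threshold `alpha` with no multiple-testing correction (the
#' reproduction choice; set `adjust = "BH"` for a false-discovery-rate
#' variant). Genes surviving all three stages are eligible for the
#' heterochrony (time-shift) test.
#'
#' @param ds an [expression_dataset()].
#' @param alpha per-stage significance threshold (default 0.05).
#' @param max_degree maximum polynomial degree.
#' @param n_grid number of grid points for the co-direction curves
#'   (default 100).
#' @param adjust `"none"` (default, the reproduction behavior) or `"BH"`
#'   to Benjamini-Hochberg-adjust each stage's p-values before thresholding.
#' @return A `cascade_result` data frame, one row per gene: `gene`, `age_p`,
#'   `divergence_p`, `codirection_r`, `codirection_p`, `passes_stage1/2/3`,
#'   `degree_pooled`, `degree_A`, `degree_B`, `reason`.
#' @export
run_cascade <- function(ds, alpha = 0.05, max_degree = 3, n_grid = 100,
                        adjust = c("none", "BH")) {
  stopifnot(inherits(ds, "expression_dataset"))
  adjust <- match.arg(adjust)
  gA <- group_slice(ds, 1)
  gB <- group_slice(ds, 2)
  lo <- max(min(gA$ages), min(gB$ages))
  hi <- min(max(gA$ages), max(gB$ages))
  if (lo >= hi) stop("the two groups' age ranges do not overlap")
  grid <- seq(lo, hi, length.out = n_grid)

  ng <- length(ds$gene_ids)
  age_p <- divergence_p <- codir_r <- codir_p <- rep(NA_real_, ng)
  deg_pool <- deg_A <- deg_B <- rep(NA_integer_, ng)
  reason <- character(ng)

  for (i in seq_len(ng)) {
    y <- ds$values[i, ]
    res <- tryCatch({
      at <- age_test(ds$ages, y, max_degree)
      dv <- ancova_divergence_test(ds$ages, y, ds$groups, max_degree)
      fitA <- fit_best_polynomial(gA$ages, y[ds$groups == levels(ds$groups)[1]],
                                  max_degree)
      fitB <- fit_best_polynomial(gB$ages, y[ds$groups == levels(ds$groups)[2]],
                                  max_degree)
      cd <- codirection_test(fitA, fitB, grid)
      list(at = at, dv = dv, cd = cd, fitA = fitA, fitB = fitB, err = NULL)
    }, error = function(e) list(err = conditionMessage(e)))
    if (!is.null(res$err)) {
      reason[i] <- res$err
      next
    }
    age_p[i] <- res$at$p
    divergence_p[i] <- res$dv$p
    codir_r[i] <- res$cd$r
    codir_p[i] <- res$cd$p
    deg_pool[i] <- res$at$fit$degree
    deg_A[i] <- res$fitA$degree
    deg_B[i] <- res$fitB$degree
    if (!res$cd$pass && nzchar(res$cd$reason)) reason[i] <- res$cd$reason
  }

  thr_age <- age_p
  thr_div <- divergence_p
  thr_cod <- codir_p
  if (adjust == "BH") {
    thr_age <- stats::p.adjust(age_p, "BH")
    thr_div <- stats::p.adjust(divergence_p, "BH")
    thr_cod <- stats::p.adjust(codir_p, "BH")
  }
  s1 <- !is.na(thr_age) & thr_age < alpha
  s2 <- s1 & !is.na(thr_div) & thr_div < alpha
  s3 <- s2 & !is.na(thr_cod) & thr_cod < alpha & !is.na(codir_r) & codir_r > 0

  out <- data.frame(gene = ds$gene_ids, age_p = age_p,
                    divergence_p = divergence_p, codirection_r = codir_r,
                    codirection_p = codir_p,
                    passes_stage1 = s1, passes_stage2 = s2, passes_stage3 = s3,
                    degree_pooled = deg_pool, degree_A = deg_A,
                    degree_B = deg_B, reason = reason,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cascade_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "eligible") <- ds$gene_ids[s3]
  out
}

#' Genes eligible for the heterochrony test
#' @param cascade a `cascade_result` from [run_cascade()].
#' @return Character vector of gene ids passing all three stages.
#' @export
eligible_genes <- function(cascade) attr(cascade, "eligible")
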