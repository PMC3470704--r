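#' Cohen's d effect size between two sample arms
#'
#' `d = (mean(case) - mean(control)) / pooled SD`, with the pooled SD
#' `sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`.
#'
#' @param case_values,control_values numeric vectors (>= 2 each).
#' @return Numeric d; `NA` with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(case_values, control_values) {
  n1 <- length(case_values)
  n2 <- length(control_values)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per arm")
  s2 <- ((n1 - 1) * stats::var(case_values) +
         (n2 - 1) * stats::var(control_values)) / (n1 + n2 - 2)
  if (s2 < 1e-300) {
    warning("zero pooled SD: Cohen's d undefined")
    return(NA_real_)
  }
  (mean(case_values) - mean(control_values)) / sqrt(s2)
}

#' Residualize effect sizes against the age correlation
#'
#' Case/control effect sizes are typically correlated, across genes, with
#' each gene's expression-age correlation (disease profiles resemble
#' hyper-aged tissue). The corrected effect size is the residual of an
#' ordinary least-squares regression of `d` on `age_corr` across genes,
#' isolating the disease effect from the shared aging signal. Residuals are
#' exactly orthogonal to `age_corr` by construction.
#'
#' @param d per-gene effect sizes (>= 10 finite values).
#' @param age_corr per-gene expression-age Pearson correlations.
#' @return Numeric residual vector (names preserved from `d`).
#' @export
corrected_effect_sizes <- function(d, age_corr) {
  if (length(d) != length(age_corr)) stop("d and age_corr lengths differ")
  if (length(d) < 10) stop("need at least 10 genes")
  if (!all(is.finite(d)) || !all(is.finite(age_corr)))
    stop("d and age_corr must be finite")
  if (stats::sd(age_corr) < 1e-12) {
    warning("constant age_corr: returning centered effect sizes")
    return(d - mean(d))
  }
  fit <- stats::lm.fit(cbind(1, age_corr), d)
  res <- fit$residuals
  names(res) <- names(d)
  res
}

#' Per-gene expression-age correlation
#'
#' @param ds an [expression_dataset()].
#' @return Named numeric vector of Pearson correlations between each gene's
#'   expression and age.
#' @export
age_correlations <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  r <- drop(stats::cor(t(ds$values), ds$ages))
  names(r) <- ds$gene_ids
  r
}

#' Compare corrected effect sizes between two gene groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of the corrected effect
#' sizes between two gene sets (e.g. genes up- versus down-regulated in the
#' accelerated group). Exact p below 50 per group without ties, normal
#' approximation with tie correction otherwise.
#'
#' @param residuals named numeric vector of corrected effect sizes.
#' @param gene_groups list of two character vectors of gene names (e.g.
#'   `list(up = ..., down = ...)`), both non-empty.
#' @return List: `W`, `p`, group medians.
#' @export
group_effect_comparison <- function(residuals, gene_groups) {
  if (length(gene_groups) != 2L) stop("gene_groups must have two elements")
  g1 <- residuals[intersect(gene_groups[[1]], names(residuals))]
  g2 <- residuals[intersect(gene_groups[[2]], names(residuals))]
  if (length(g1) == 0L || length(g2) == 0L)
    stop("empty gene group: ",
         names(gene_groups)[c(length(g1), length(g2)) == 0][1])
  exact <- length(g1) < 50 && length(g2) < 50 &&
    !any(duplicated(c(g1, g2)))
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g2, alternative = "two.sided", exact = exact))
  list(W = unname(wt$statistic), p = wt$p.value,
       median_1 = stats::median(g1), median_2 = stats::median(g2))
}

#' F-test for unequal residual variance between groups
#'
#' Compares the two groups' dispersion around their own fitted age
#' trajectories: `F = s2_A / s2_B` where each `s2` is the residual variance
#' of that group's best-polynomial fit, with `(nA - dA - 1, nB - dB - 1)`
#' degrees of freedom. Residual (detrended) variance is used so that
#' trajectory divergence between the groups is not mistaken for dispersion;
#' set `detrend = FALSE` to compare raw variances.
#'
#' @param valuesA,valuesB expression values per group.
#' @param agesA,agesB ages per group (required when `detrend = TRUE`).
#' @param detrend remove each group's own fitted age trajectory first
#'   (default TRUE).
#' @param max_degree maximum polynomial degree for the per-group fits.
#' @return List: `F`, `df`, `p_A_greater`, `p_B_greater`.
#' @export
variance_f_test <- function(valuesA, valuesB, agesA = NULL, agesB = NULL,
                            detrend = TRUE, max_degree = 3) {
  if (length(valuesA) < 3 || length(valuesB) < 3)
    stop("need at least 3 samples per group")
  if (detrend) {
    if (is.null(agesA) || is.null(agesB))
      stop("detrend = TRUE requires agesA and agesB")
    fA <- fit_best_polynomial(agesA, valuesA, max_degree)
    fB <- fit_best_polynomial(agesB, valuesB, max_degree)
    dfA <- fA$n - fA$degree - 1
    dfB <- fB$n - fB$degree - 1
    s2A <- fA$rss / dfA
    s2B <- fB$rss / dfB
  } else {
    dfA <- length(valuesA) - 1
    dfB <- length(valuesB) - 1
    s2A <- stats::var(valuesA)
    s2B <- stats::var(valuesB)
  }
  if (dfA < 1 || dfB < 1) stop("non-positive residual degrees of freedom")
  Fstat <- s2A / s2B
  list(F = Fstat, df = c(dfA, dfB),
       p_A_greater = stats::pf(Fstat, dfA, dfB, lower.tail = FALSE),
       p_B_greater = stats::pf(Fstat, dfA, dfB, lower.tail = TRUE))
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between `setA` and `setB` drawn from `universe`, with the odds
#' ratio of the 2x2 membership table (Haldane-Anscombe 0.5 correction when
#' any cell is zero).
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes (non-empty).
#' @return An `overlap_result`: `odds_ratio`, `p`, `table` (2x2 counts),
#'   `overlap`, `expected`.
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  setA <- unique(intersect(setA, universe))
  setB <- unique(intersect(setB, universe))
  N <- length(universe)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c_ <- length(setB) - a
  d <- N - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(c("inA", "notA"), c("inB", "notB")))
  or <- if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
        else (a * d) / (b * c_)
  p <- stats::phyper(a - 1, length(setA), N - length(setA), length(setB),
                     lower.tail = FALSE)
  structure(list(odds_ratio = or, p = p, table = tab, overlap = a,
                 expected = length(setA) * length(setB) / N),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: overlap = %d (expected %.2f), OR = %.3g, p = %.3g\n",
              x$overlap, x$expected, x$odds_ratio, x$p))
  invisible(x)
}

#' Cluster genes by trajectory or shift profile
#'
#' Agglomerative hierarchical clustering (average linkage) under correlation
#' distance `1 - r` between feature rows, cut at `k` clusters. Typical
#' feature matrices: concatenated per-group standardized fitted curves on a
#' shared grid, or per-grid-point shift profiles.
#'
#' @param features numeric matrix, one row per gene.
#' @param k number of clusters (`1 <= k <=` number of genes).
#' @return Named integer vector of cluster labels; the `hclust` tree is in
#'   attribute `"tree"`.
#' @export
cluster_genes <- function(features, k) {
  features <- as.matrix(features)
  if (k > nrow(features)) stop("k exceeds the number of genes")
  if (k < 1) stop("k must be >= 1")
  if (nrow(features) == 1L) {
    lab <- stats::setNames(1L, rownames(features))
    return(lab)
  }
  cr <- suppressWarnings(stats::cor(t(features)))
  cr[!is.finite(cr)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cr), method = "average")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "tree") <- hc
  labels
}

#' Bootstrap-stability clustering of samples
#'
#' Hierarchically clusters samples (correlation distance on per-gene
#' standardized expression, average linkage), then resamples genes with
#' replacement `n_boot` times, reclusters, and records for every sample
#' pair the frequency of landing in the same cluster at a 2-cluster cut.
#' The consensus 2-group partition clusters the co-assignment distance.
#' By default the pooled age trajectory of each gene is removed first
#' (`detrend = TRUE`), so the partition reflects structure beyond the
#' shared aging trajectory (e.g. a divergent subpopulation) rather than a
#' young/old split.
#'
#' @param ds an [expression_dataset()].
#' @param genes optional gene ids to restrict to (>= 10 genes).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed optional integer seed.
#' @param detrend remove each gene's pooled fitted age trajectory before
#'   standardizing (default TRUE).
#' @param max_degree maximum polynomial degree for the detrending fits.
#' @return List: `tree` (`hclust` of samples), `stability` (sample x sample
#'   co-assignment frequencies), `partition` (named 2-group consensus
#'   labels), `n_boot`.
#' @export
bootstrap_cluster_samples <- function(ds, genes = NULL, n_boot = 1000,
                                      seed = NULL, detrend = TRUE,
                                      max_degree = 3) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.null(seed)) set.seed(seed)
  X <- if (is.null(genes)) ds$values
       else ds$values[intersect(genes, ds$gene_ids), , drop = FALSE]
  if (nrow(X) < 10) stop("need at least 10 genes")
  if (ncol(X) < 2) stop("need at least 2 samples")
  if (detrend) {
    for (i in seq_len(nrow(X))) {
      fit <- fit_best_polynomial(ds$ages, X[i, ], max_degree)
      X[i, ] <- X[i, ] - predict(fit, ds$ages)
    }
  }
  Z <- standardize_genes(X)

  cluster_once <- function(M) {
    cr <- suppressWarnings(stats::cor(M))
    cr[!is.finite(cr)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cr), method = "average")
    list(hc = hc, labels = stats::cutree(hc, k = 2))
  }
  base <- cluster_once(Z)
  ns <- ncol(Z)
  co <- matrix(0, ns, ns, dimnames = list(colnames(Z), colnames(Z)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(Z), replace = TRUE)
    lab <- cluster_once(Z[idx, , drop = FALSE])$labels
    co <- co + outer(lab, lab, `==`)
  }
  stability <- co / n_boot
  cons <- stats::hclust(stats::as.dist(1 - stability), method = "average")
  partition <- stats::cutree(cons, k = 2)
  list(tree = base$hc, stability = stability, partition = partition,
       n_boot = n_boot)
}
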