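#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' row-wise mean of the sorted columns. Delegates to
#' [limma::normalizeQuantiles()] after validating the input; row and column
#' order are preserved.
#'
#' @param matrix numeric gene x sample matrix with finite entries and at
#'   least 2 samples.
#' @return Matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 samples")
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-finite value at gene ",
         if (is.null(rownames(m))) bad[1] else rownames(m)[bad[1]],
         ", sample ",
         if (is.null(colnames(m))) bad[2] else colnames(m)[bad[2]])
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Standardize each gene to mean 0, SD 1
#'
#' Uses the sample standard deviation (n - 1 denominator). Zero-variance
#' genes are returned as all zeros and recorded in the `"flagged_genes"`
#' attribute.
#'
#' @param matrix numeric gene x sample matrix.
#' @return Standardized matrix with attribute `flagged_genes` (row names, or
#'   indices when unnamed, of constant genes).
#' @export
standardize_genes <- function(matrix) {
  m <- as.matrix(matrix)
  mu <- rowMeans(m)
  centered <- m - mu
  sds <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  flat <- sds < 1e-12
  sds[flat] <- 1
  out <- centered / sds
  out[flat, ] <- 0
  attr(out, "flagged_genes") <-
    if (is.null(rownames(m))) which(flat) else rownames(m)[flat]
  out
}

#' Verify group labels against marker genes
#'
#' Computes, per sample, the mean standardized expression of a marker set
#' expected high in group A (`marker_up`, e.g. XIST for a female group) and
#' one expected high in group B (`marker_down`, e.g. Y-linked genes), and
#' flags samples whose marker contrast deviates from their labeled group's
#' distribution by more than `z_threshold` standard deviations in the
#' direction of the other group. Group means/SDs are computed leaving the
#' assessed sample out, so a single mislabeled sample cannot mask itself.
#'
#' @param ds an [expression_dataset()].
#' @param marker_up,marker_down gene ids expected high in group A
#'   (first level) and group B respectively.
#' @param z_threshold flagging threshold in SD units (default 3).
#' @return Data frame (one row per sample): `sample`, `group`,
#'   `marker_score` (mean z of `marker_up` minus mean z of `marker_down`),
#'   `marker_flag` (`"ok"` or `"mislabeled-suspect"`), `reason`.
#' @export
verify_group_markers <- function(ds, marker_up, marker_down, z_threshold = 3) {
  stopifnot(inherits(ds, "expression_dataset"))
  up <- intersect(marker_up, ds$gene_ids)
  down <- intersect(marker_down, ds$gene_ids)
  if (length(up) + length(down) == 0L)
    stop("no marker genes found in the dataset")
  z <- standardize_genes(ds$values)
  score_up <- if (length(up)) colMeans(z[up, , drop = FALSE]) else 0
  score_down <- if (length(down)) colMeans(z[down, , drop = FALSE]) else 0
  score <- score_up - score_down  # high in group A, low in group B

  isA <- ds$groups == levels(ds$groups)[1]
  flag <- character(ncol(ds$values))
  reason <- character(ncol(ds$values))
  for (s in seq_along(score)) {
    own <- if (isA[s]) which(isA) else which(!isA)
    own <- setdiff(own, s)
    mu <- mean(score[own])
    sdv <- stats::sd(score[own])
    if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1e-12
    zscore <- (score[s] - mu) / sdv
    # wrong direction: toward the other group's side of its own group mean
    wrong <- if (isA[s]) zscore < -z_threshold else zscore > z_threshold
    if (is.finite(z_threshold) && wrong) {
      flag[s] <- "mislabeled-suspect"
      reason[s] <- sprintf("marker contrast %.2f SD %s its %s-group mean",
                           abs(zscore), if (isA[s]) "below" else "above",
                           as.character(ds$groups[s]))
    } else {
      flag[s] <- "ok"
      reason[s] <- ""
    }
  }
  data.frame(sample = ds$sample_ids, group = as.character(ds$groups),
             marker_score = score, marker_flag = flag, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen samples for outlying expression profiles
#'
#' For each sample, counts the genes in which the sample lies more than
#' `sd_cutoff` standard deviations from that gene's cross-sample mean, and
#' flags samples whose count reaches `min_extreme_genes`. By default the
#' flagging floor is the larger of the 99th percentile of per-sample counts
#' and 3% of the gene count, so the rule adapts to platform size. The first
#' two principal-component coordinates are reported for inspection.
#'
#' @param ds an [expression_dataset()].
#' @param sd_cutoff per-gene z threshold defining an extreme value.
#' @param min_extreme_genes absolute flagging floor; `NULL` (default) uses
#'   `max(quantile(counts, .99), ceiling(0.03 * n_genes))`.
#' @return Data frame per sample: `sample`, `n_extreme_genes`,
#'   `outlier_flag`, `pc1`, `pc2`, `reason`; attribute `threshold` holds the
#'   flagging floor used.
#' @export
detect_outliers <- function(ds, sd_cutoff = 3, min_extreme_genes = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ncol(ds$values) < 3L) stop("outlier screening needs at least 3 samples")
  z <- standardize_genes(ds$values)
  counts <- colSums(abs(z) > sd_cutoff)
  floor_abs <- ceiling(0.03 * nrow(ds$values))
  thr <- if (is.null(min_extreme_genes))
    max(stats::quantile(counts, 0.99, names = FALSE), floor_abs)
  else min_extreme_genes
  flag <- counts >= thr & counts > 0
  pca <- stats::prcomp(t(ds$values), center = TRUE, scale. = FALSE)
  pcs <- pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE]
  out <- data.frame(
    sample = ds$sample_ids,
    n_extreme_genes = as.integer(counts),
    outlier_flag = flag,
    pc1 = pcs[, 1],
    pc2 = if (ncol(pcs) > 1) pcs[, 2] else 0,
    reason = ifelse(flag, sprintf("%d genes beyond %.3g SD (floor %d)",
                                  counts, sd_cutoff, as.integer(thr)), ""),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}

#' Write a sample QC report as tab-delimited text
#'
#' Joins marker verification and outlier screening into one table.
#'
#' @param outlier_report result of [detect_outliers()].
#' @param marker_report optional result of [verify_group_markers()].
#' @param path output file path.
#' @export
write_qc_report <- function(outlier_report, marker_report = NULL, path) {
  tab <- outlier_report
  if (!is.null(marker_report)) {
    tab$marker_flag <- marker_report$marker_flag[
      match(tab$sample, marker_report$sample)]
    mreason <- marker_report$reason[match(tab$sample, marker_report$sample)]
    tab$reason <- trimws(paste(tab$reason, mreason, sep = "; "))
    tab$reason <- sub("^; |; $", "", tab$reason)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
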