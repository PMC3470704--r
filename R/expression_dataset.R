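#' Two-group expression age-series container
#'
#' The universal input of the pipeline: a gene x sample matrix of (log-scale)
#' expression values together with per-sample ages (years) and a two-level
#' group label. Group "A" (the first factor level) is, by convention, the
#' group a positive time-shift accelerates; mapping "A"/"B" onto biological
#' labels such as female/male is the caller's concern.
#'
#' @param values numeric gene x sample matrix; rownames are gene ids and
#'   colnames sample ids (generated when absent).
#' @param ages numeric vector of ages in years, one per sample.
#' @param groups two-level factor (or coercible) of group labels per sample.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `ages`, `groups`, `gene_ids`, `sample_ids`.
#' @export
expression_dataset <- function(values, ages, groups) {
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ", colnames(values)[duplicated(colnames(values))][1])
  if (length(ages) != ncol(values))
    stop("ages length (", length(ages), ") does not match sample count (",
         ncol(values), ")")
  if (length(groups) != ncol(values))
    stop("groups length does not match sample count")
  if (!all(is.finite(ages)))
    stop("non-finite age for sample ", colnames(values)[which(!is.finite(ages))[1]])
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels, got: ",
         paste(levels(groups), collapse = ", "))
  if (any(table(groups) < 3L))
    stop("each group needs at least 3 samples")
  structure(
    list(values = values, ages = as.numeric(ages), groups = groups,
         gene_ids = rownames(values), sample_ids = colnames(values)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                                 tabulate(x$groups)), collapse = ", "), "\n")
  cat("  ages:", sprintf("%.1f-%.1f years", min(x$ages), max(x$ages)), "\n")
  invisible(x)
}

# Values/ages for one group; level may be an index (1/2) or a level name.
group_slice <- function(ds, level) {
  lev <- if (is.numeric(level)) levels(ds$groups)[level] else as.character(level)
  sel <- ds$groups == lev
  list(values = ds$values[, sel, drop = FALSE], ages = ds$ages[sel], level = lev)
}

#' Write an expression dataset as tab-delimited text
#'
#' Writes `expression.tsv` (genes in rows, first column `gene`, one column per
#' sample) and `metadata.tsv` (columns `sample`, `age`, `group`) into `path`.
#' Values are written with 15 significant digits so the round trip is lossless
#' well beyond 12 significant digits.
#'
#' @param ds an [expression_dataset()].
#' @param path directory to write into (created if missing).
#' @return Invisibly, the paths of the two files written.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  expr_file <- file.path(path, "expression.tsv")
  meta_file <- file.path(path, "metadata.tsv")
  tab <- data.frame(gene = ds$gene_ids,
                    format(ds$values, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene", ds$sample_ids)
  utils::write.table(tab, expr_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample = ds$sample_ids,
                     age = format(ds$ages, digits = 15, trim = TRUE),
                     group = as.character(ds$groups),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = expr_file, metadata = meta_file))
}

#' Read an expression dataset written by [write_dataset()]
#'
#' @param path directory containing `expression.tsv` and `metadata.tsv`.
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(path) {
  expr_file <- file.path(path, "expression.tsv")
  meta_file <- file.path(path, "metadata.tsv")
  for (f in c(expr_file, meta_file))
    if (!file.exists(f)) stop("missing file: ", f)
  tab <- utils::read.delim(expr_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || colnames(tab)[1] != "gene")
    stop("expression table must have a leading 'gene' column")
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  if (!all(c("sample", "age", "group") %in% colnames(meta)))
    stop("metadata must have columns sample, age, group")
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    bad <- colnames(values)[which(!apply(values, 2, is.numeric))[1]]
    stop("non-numeric expression values in sample ", bad)
  }
  rownames(values) <- tab$gene
  missing_meta <- setdiff(colnames(values), meta$sample)
  if (length(missing_meta))
    stop("sample missing from metadata: ", paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(meta$sample, colnames(values))
  if (length(extra_meta))
    stop("metadata sample absent from matrix: ",
         paste(extra_meta, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample), ]
  expression_dataset(values, meta$age, meta$group)
}
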