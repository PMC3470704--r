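#' Heterochrony test over a set of genes
#'
#' Runs [heterochrony_test()] for each gene, deriving a deterministic
#' per-gene seed from `seed` so results are reproducible and independent of
#' gene order.
#'
#' @param ds an [expression_dataset()].
#' @param genes gene ids to test (typically [eligible_genes()] of a
#'   cascade).
#' @param alpha,n_null,n_grid,slack,max_degree,null_mode see
#'   [heterochrony_test()].
#' @param seed integer base seed; gene `k` uses `seed + k`.
#' @return Data frame, one row per gene: `gene`, `p_A_to_B`, `p_B_to_A`,
#'   `significant`, `mean_shift_years`, `direction`, `n_null`, `seed`,
#'   `reason`.
#' @export
heterochrony_scan <- function(ds, genes, alpha = 0.05, n_null = 1000,
                              seed = 1L, n_grid = 50, slack = 5,
                              max_degree = 3,
                              null_mode = c("parametric", "permutation")) {
  null_mode <- match.arg(null_mode)
  rows <- lapply(seq_along(genes), function(k) {
    gseed <- (as.integer(seed) + k) %% .Machine$integer.max
    res <- tryCatch(
      heterochrony_test(ds, genes[k], alpha = alpha, n_null = n_null,
                        seed = gseed, n_grid = n_grid, slack = slack,
                        max_degree = max_degree, null_mode = null_mode),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(gene = genes[k], p_A_to_B = NA_real_,
                        p_B_to_A = NA_real_, significant = FALSE,
                        mean_shift_years = NA_real_, direction = "none",
                        n_null = n_null, seed = gseed,
                        reason = "test failed", stringsAsFactors = FALSE))
    data.frame(gene = res$gene, p_A_to_B = res$p_A_to_B,
               p_B_to_A = res$p_B_to_A, significant = res$significant,
               mean_shift_years = res$mean_shift, direction = res$direction,
               n_null = res$n_null, seed = gseed, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stage-count summary of a pipeline run
#'
#' Tabulates genes passing each cascade stage and, among significantly
#' heterochronic genes, the counts and percentages per direction of
#' acceleration.
#'
#' @param cascade a `cascade_result` from [run_cascade()].
#' @param het optional data frame from [heterochrony_scan()].
#' @return Data frame with columns `stage`, `count`, `percent` (percent of
#'   the relevant parent set).
#' @export
summarize_counts <- function(cascade, het = NULL) {
  n <- nrow(cascade)
  n1 <- sum(cascade$passes_stage1)
  n2 <- sum(cascade$passes_stage2)
  n3 <- sum(cascade$passes_stage3)
  pct <- function(x, base) if (base > 0) 100 * x / base else 0
  out <- data.frame(
    stage = c("genes", "age_related", "divergent", "codirectional"),
    count = c(n, n1, n2, n3),
    percent = c(100, pct(n1, n), pct(n2, n1), pct(n3, n2)),
    stringsAsFactors = FALSE)
  if (!is.null(het)) {
    nsig <- sum(het$significant)
    nA <- sum(het$significant & het$direction == "A-accelerated")
    nB <- sum(het$significant & het$direction == "B-accelerated")
    out <- rbind(out, data.frame(
      stage = c("heterochronic", "A_accelerated", "B_accelerated"),
      count = c(nsig, nA, nB),
      percent = c(pct(nsig, n3), pct(nA, nsig), pct(nB, nsig)),
      stringsAsFactors = FALSE))
  }
  out
}

#' Parse a flat key = value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; numeric-looking
#' values are converted. Keys mirror the arguments of [run_pipeline()].
#'
#' @param path file path.
#' @return Named list.
#' @export
parse_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num
    else if (v %in% c("TRUE", "FALSE", "true", "false")) as.logical(toupper(v))
    else v
  })
  stats::setNames(vals, vapply(kv, `[`, "", 1))
}

#' Run the full heterochrony pipeline
#'
#' Orchestrates: input (simulate via [generate_dataset()] or read via
#' [read_dataset()]) -> optional sample QC -> cascade -> heterochrony scan
#' -> stage-count summary. All stage tables, a run manifest recording
#' seeds/thresholds/counts, and a log are written to `out_dir`; a rerun
#' with an identical config reproduces identical tables.
#'
#' @param config a named list (or path to a `key = value` file parsed with
#'   [parse_run_config()]) with entries: either `sim_config` (a
#'   [simulation_config()]) or `input_dir` (directory for
#'   [read_dataset()]); optional `out_dir` (default: no files written),
#'   `alpha` (0.05), `max_degree` (3), `n_grid` (50), `slack` (5), `n_null`
#'   (1000), `seed` (1), `run_qc` (TRUE), `drop_outliers` (FALSE),
#'   `null_mode` ("parametric").
#' @return Invisibly, a list: `dataset`, `truth` (when simulated), `qc`,
#'   `cascade`, `heterochrony`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- parse_run_config(config)
  defaults <- list(alpha = 0.05, max_degree = 3, n_grid = 50, slack = 5,
                   n_null = 1000, seed = 1L, run_qc = TRUE,
                   drop_outliers = FALSE, null_mode = "parametric",
                   out_dir = NULL)
  cf <- utils::modifyList(defaults, config)

  log_lines <- character(0)
  log_step <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  truth <- NULL
  if (!is.null(cf$sim_config)) {
    log_step("simulate: n_genes = ", cf$sim_config$n_genes,
             ", seed = ", cf$sim_config$seed)
    sim <- generate_dataset(cf$sim_config)
    ds <- sim$dataset
    truth <- sim$truth
  } else if (!is.null(cf$input_dir)) {
    log_step("read dataset from ", cf$input_dir)
    ds <- read_dataset(cf$input_dir)
  } else {
    stop("config must provide sim_config or input_dir")
  }

  qc <- NULL
  if (isTRUE(cf$run_qc)) {
    qc <- detect_outliers(ds)
    log_step("qc: ", sum(qc$outlier_flag), " outlier sample(s) flagged")
    if (isTRUE(cf$drop_outliers) && any(qc$outlier_flag)) {
      keep <- !qc$outlier_flag
      ds <- expression_dataset(ds$values[, keep, drop = FALSE],
                               ds$ages[keep], ds$groups[keep])
      log_step("qc: dropped ", sum(!keep), " sample(s)")
    }
  }

  cascade <- run_cascade(ds, alpha = cf$alpha, max_degree = cf$max_degree)
  elig <- eligible_genes(cascade)
  log_step("cascade: ", sum(cascade$passes_stage1), " age-related, ",
           sum(cascade$passes_stage2), " divergent, ",
           length(elig), " eligible for the heterochrony test")

  het <- heterochrony_scan(ds, elig, alpha = cf$alpha, n_null = cf$n_null,
                           seed = cf$seed, n_grid = cf$n_grid,
                           slack = cf$slack, max_degree = cf$max_degree,
                           null_mode = cf$null_mode)
  log_step("heterochrony: ", sum(het$significant), " significant of ",
           nrow(het), " tested")

  summary_tab <- summarize_counts(cascade, het)
  manifest <- c(
    sprintf("package_version = %s",
            as.character(utils::packageVersion("heterochron"))),
    sprintf("alpha = %g", cf$alpha),
    sprintf("max_degree = %d", as.integer(cf$max_degree)),
    sprintf("n_grid = %d", as.integer(cf$n_grid)),
    sprintf("slack = %d", as.integer(cf$slack)),
    sprintf("n_null = %d", as.integer(cf$n_null)),
    sprintf("seed = %d", as.integer(cf$seed)),
    sprintf("null_mode = %s", cf$null_mode),
    if (!is.null(truth)) sprintf("sim_seed = %d",
                                 as.integer(cf$sim_config$seed)),
    sprintf("n_genes = %d", nrow(ds$values)),
    sprintf("n_samples = %d", ncol(ds$values)),
    vapply(seq_len(nrow(summary_tab)), function(i)
      sprintf("count_%s = %d", summary_tab$stage[i],
              as.integer(summary_tab$count[i])), ""))

  if (!is.null(cf$out_dir)) {
    if (!dir.exists(cf$out_dir)) dir.create(cf$out_dir, recursive = TRUE)
    wt <- function(tab, name)
      utils::write.table(tab, file.path(cf$out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(truth)) {
      write_dataset(ds, cf$out_dir)
      write_truth(truth, file.path(cf$out_dir, "truth.tsv"))
    }
    if (!is.null(qc)) wt(qc, "qc_report.tsv")
    wt(as.data.frame(cascade), "cascade.tsv")
    wt(het, "heterochrony.tsv")
    wt(summary_tab, "summary.tsv")
    writeLines(manifest, file.path(cf$out_dir, "manifest.txt"))
    writeLines(log_lines, file.path(cf$out_dir, "run.log"))
  }

  invisible(list(dataset = ds, truth = truth, qc = qc, cascade = cascade,
                 heterochrony = het, summary = summary_tab,
                 manifest = manifest))
}
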