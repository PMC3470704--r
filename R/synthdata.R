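#' Configuration for the two-group age-series simulator
#'
#' Defines the structure of a synthetic expression age-series: how many genes
#' change with age, how many of those diverge between the two groups, how many
#' of the divergent genes are truly heterochronic (time-shifted), and the
#' noise model. Defaults emulate a human brain aging study design: two groups
#' of ~20 individuals each with ages spanning 20-99 years, a sizeable minority
#' of age-related genes, and decade-scale planted time shifts.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (at least 4, so a cubic plus intercept
#'   is estimable).
#' @param age_min,age_max age range in years.
#' @param age_sampling `"uniform"` (default) or `"from_list"`; in the latter
#'   case supply `ages_A` and `ages_B`.
#' @param ages_A,ages_B explicit age vectors when `age_sampling = "from_list"`.
#' @param frac_age_related proportion of genes with a true age trajectory.
#' @param frac_divergent_given_age_related proportion of age-related genes
#'   that differ between groups.
#' @param frac_heterochronic_given_divergent proportion of divergent genes
#'   whose divergence is a time shift rather than a constant offset.
#' @param direction_bias probability that a planted shift accelerates group A.
#' @param shift_years planted shift magnitude in years: a single value
#'   (fixed) or a length-2 range sampled uniformly.
#' @param heterochrony_mode_mix proportion of heterochronic genes that are
#'   onset-shifted (trajectory translated in age); the rest are rate-scaled
#'   (trajectory runs faster, anchored at `age_min`).
#' @param trajectory_degree_weights weights over polynomial degrees 0-3; for
#'   age-related genes the weights on degrees 1-3 are renormalized (a flat
#'   gene cannot be age-related).
#' @param signal_amplitude standard deviation of the noiseless trajectory
#'   across the age range, in expression units (so
#'   `signal_amplitude / noise_sd` is the per-gene signal-to-noise ratio).
#' @param noise_sd additive Gaussian noise standard deviation per observation.
#' @param divergence_offset constant between-group offset (expression units)
#'   planted in divergent, non-heterochronic genes; sign random per gene.
#' @param frac_variance_inflated proportion of genes whose group-A noise
#'   variance is inflated.
#' @param variance_inflation_factor variance ratio (>= 1) for inflated genes.
#' @param subpopulation_fraction proportion of group-A samples forming a
#'   divergent subpopulation: only these samples express the planted
#'   acceleration, the remaining group-A samples follow the group-B curve.
#' @param seed integer master seed; identical config + seed gives
#'   byte-identical output.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 12000, n_per_group = 20,
                              age_min = 20, age_max = 99,
                              age_sampling = c("uniform", "from_list"),
                              ages_A = NULL, ages_B = NULL,
                              frac_age_related = 0.4,
                              frac_divergent_given_age_related = 0.35,
                              frac_heterochronic_given_divergent = 0.27,
                              direction_bias = 0.5,
                              shift_years = 10,
                              heterochrony_mode_mix = 0.5,
                              trajectory_degree_weights = c(0, 0.6, 0.25, 0.15),
                              signal_amplitude = 1,
                              noise_sd = 0.25,
                              divergence_offset = 0.75,
                              frac_variance_inflated = 0,
                              variance_inflation_factor = 1,
                              subpopulation_fraction = 0,
                              seed = 1L) {
  age_sampling <- match.arg(age_sampling)
  props <- c(frac_age_related = frac_age_related,
             frac_divergent_given_age_related = frac_divergent_given_age_related,
             frac_heterochronic_given_divergent = frac_heterochronic_given_divergent,
             direction_bias = direction_bias,
             heterochrony_mode_mix = heterochrony_mode_mix,
             frac_variance_inflated = frac_variance_inflated,
             subpopulation_fraction = subpopulation_fraction)
  bad <- names(props)[props < 0 | props > 1]
  if (length(bad)) stop("proportions must lie in [0,1]: ",
                        paste(bad, collapse = ", "))
  if (age_min >= age_max) stop("age_min must be < age_max")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (variance_inflation_factor < 1)
    stop("variance_inflation_factor must be >= 1")
  if (!length(shift_years) %in% 1:2 || any(shift_years < 0))
    stop("shift_years must be a non-negative value or range")
  if (length(shift_years) == 2 && shift_years[1] > shift_years[2])
    stop("shift_years range must be increasing")
  if (length(trajectory_degree_weights) != 4 ||
      any(trajectory_degree_weights < 0) ||
      sum(trajectory_degree_weights[2:4]) <= 0)
    stop("trajectory_degree_weights must be 4 non-negative weights with mass on degrees 1-3")
  if (n_per_group < 4)
    stop("n_per_group must be >= 4 (a cubic plus intercept needs 4 points per group)")
  if (age_sampling == "from_list") {
    if (is.null(ages_A) || is.null(ages_B))
      stop("age_sampling = 'from_list' requires ages_A and ages_B")
    if (length(ages_A) != n_per_group || length(ages_B) != n_per_group)
      stop("ages_A/ages_B must each have n_per_group entries")
  }
  structure(as.list(environment()), class = "simulation_config")
}

# Evaluate a polynomial with coefficients in the centered-age basis
# (intercept first) at the given ages.
eval_poly <- function(coefficients, ages, center) {
  u <- ages - center
  drop(outer(u, seq_along(coefficients) - 1, `^`) %*% coefficients)
}

# Random trajectory of the given degree, rescaled so the curve's standard
# deviation over a dense reference grid equals `amplitude`. Coefficients are
# in the centered basis u = age - midpoint. Returns the coefficient vector.
random_trajectory <- function(degree, age_min, age_max, amplitude, baseline) {
  mid <- (age_min + age_max) / 2
  half <- (age_max - age_min) / 2
  # draw shape coefficients on the scaled variable u/half so all degrees
  # contribute comparably, then convert to the u basis
  raw <- stats::rnorm(degree)
  coef_u <- c(0, raw / half^seq_len(degree))
  ref <- seq(age_min, age_max, length.out = 201)
  g <- eval_poly(coef_u, ref, mid)
  s <- stats::sd(g)
  if (s < 1e-12) { # pathological draw: fall back to a pure linear ramp
    coef_u <- c(0, 1 / half, rep(0, degree - 1))[seq_len(degree + 1)]
    g <- eval_poly(coef_u, ref, mid)
    s <- stats::sd(g)
  }
  coef <- coef_u * amplitude / s
  coef[1] <- baseline - mean(g) * amplitude / s
  coef
}

#' Generate a synthetic two-group expression age-series with known truth
#'
#' Plants a configurable cascade of structure: age-related genes follow a
#' polynomial trajectory shared by both groups; a subset of those diverge
#' between groups, either by a constant offset or by true heterochrony.
#' Onset-shift genes translate the accelerated group's trajectory in age
#' (group A follows `f(age + shift)` while B follows `f(age)`); rate-scale
#' genes run the accelerated group's trajectory faster, anchored at the
#' youngest age, with the rate chosen to realize the configured shift at the
#' age-range midpoint. Gaussian noise is added to every observation.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (a data frame with one row per gene: `gene`, `is_age_related`,
#'   `is_divergent`, `is_heterochronic`, `true_mode`, `true_shift` (signed
#'   years, positive = group A accelerated), `trajectory_degree`,
#'   `base_coefficients` (centered-basis coefficients joined by ";"),
#'   `is_variance_inflated`, plus attributes `age_center` and
#'   `subpop_samples`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_per_group
  mid <- (cf$age_min + cf$age_max) / 2

  if (cf$age_sampling == "uniform") {
    agesA <- sort(stats::runif(n, cf$age_min, cf$age_max))
    agesB <- sort(stats::runif(n, cf$age_min, cf$age_max))
  } else {
    agesA <- as.numeric(cf$ages_A)
    agesB <- as.numeric(cf$ages_B)
  }
  ages <- c(agesA, agesB)
  groups <- rep(c("A", "B"), each = n)
  sample_ids <- c(sprintf("A%03d", seq_len(n)), sprintf("B%03d", seq_len(n)))
  gene_ids <- sprintf("g%05d", seq_len(cf$n_genes))

  n_sub <- round(cf$subpopulation_fraction * n)
  subpop <- if (n_sub > 0) sample(seq_len(n), n_sub) else integer(0)

  is_age <- stats::runif(cf$n_genes) < cf$frac_age_related
  is_div <- is_age & stats::runif(cf$n_genes) < cf$frac_divergent_given_age_related
  is_het <- is_div & stats::runif(cf$n_genes) < cf$frac_heterochronic_given_divergent
  accel_A <- stats::runif(cf$n_genes) < cf$direction_bias
  onset <- stats::runif(cf$n_genes) < cf$heterochrony_mode_mix
  shift_mag <- if (length(cf$shift_years) == 1) rep(cf$shift_years, cf$n_genes)
               else stats::runif(cf$n_genes, cf$shift_years[1], cf$shift_years[2])
  degw <- cf$trajectory_degree_weights
  degree <- ifelse(is_age,
                   sample(1:3, cf$n_genes, replace = TRUE,
                          prob = degw[2:4] / sum(degw[2:4])),
                   0L)
  offset_sign <- sample(c(-1, 1), cf$n_genes, replace = TRUE)
  is_vinf <- stats::runif(cf$n_genes) < cf$frac_variance_inflated
  baselines <- stats::rnorm(cf$n_genes, mean = 8, sd = 1)

  signal <- matrix(0, cf$n_genes, 2 * n,
                   dimnames = list(gene_ids, sample_ids))
  coef_str <- character(cf$n_genes)
  true_shift <- numeric(cf$n_genes)
  true_mode <- rep("none", cf$n_genes)
  idxA <- seq_len(n)
  idxB <- n + seq_len(n)

  for (g in seq_len(cf$n_genes)) {
    if (!is_age[g]) {
      coef <- baselines[g]
      signal[g, ] <- coef
      coef_str[g] <- format_coef(coef)
      next
    }
    coef <- random_trajectory(degree[g], cf$age_min, cf$age_max,
                              cf$signal_amplitude, baselines[g])
    coef_str[g] <- format_coef(coef)
    effA <- agesA
    effB <- agesB
    base_offset_A <- 0
    if (is_het[g]) {
      d <- shift_mag[g]
      true_shift[g] <- if (accel_A[g]) d else -d
      true_mode[g] <- if (onset[g]) "onset-shift" else "rate-scale"
      if (onset[g]) {
        if (accel_A[g]) effA <- agesA + d else effB <- agesB + d
      } else {
        k <- 1 + d / (mid - cf$age_min)
        if (accel_A[g]) effA <- cf$age_min + k * (agesA - cf$age_min)
        else            effB <- cf$age_min + k * (agesB - cf$age_min)
      }
    } else if (is_div[g]) {
      base_offset_A <- offset_sign[g] * cf$divergence_offset
    }
    valsA <- eval_poly(coef, effA, mid) + base_offset_A
    valsB <- eval_poly(coef, effB, mid)
    if (is_het[g] && accel_A[g] && length(subpop)) {
      # only the planted subpopulation expresses the acceleration
      keepB <- setdiff(seq_len(n), subpop)
      valsA[keepB] <- eval_poly(coef, agesA[keepB], mid)
    }
    signal[g, idxA] <- valsA
    signal[g, idxB] <- valsB
  }

  sdmat <- matrix(cf$noise_sd, cf$n_genes, 2 * n)
  if (any(is_vinf) && cf$variance_inflation_factor > 1)
    sdmat[is_vinf, idxA] <- cf$noise_sd * sqrt(cf$variance_inflation_factor)
  noise <- matrix(stats::rnorm(length(signal), sd = sdmat),
                  cf$n_genes, 2 * n)
  values <- signal + noise

  truth <- data.frame(
    gene = gene_ids,
    is_age_related = is_age,
    is_divergent = is_div,
    is_heterochronic = is_het,
    true_mode = ifelse(is_het, true_mode, "none"),
    true_shift = ifelse(is_het, true_shift, 0),
    trajectory_degree = degree,
    base_coefficients = coef_str,
    is_variance_inflated = is_vinf,
    stringsAsFactors = FALSE)
  attr(truth, "age_center") <- mid
  attr(truth, "subpop_samples") <- sample_ids[subpop]

  list(dataset = expression_dataset(values, ages, groups), truth = truth)
}

format_coef <- function(coef) paste(format(coef, digits = 15), collapse = ";")

#' Parse the `base_coefficients` column of a truth table
#'
#' @param truth the truth data frame from [generate_dataset()].
#' @param gene gene id.
#' @return Numeric coefficient vector (centered-age basis, intercept first).
#' @export
truth_coefficients <- function(truth, gene) {
  row <- match(gene, truth$gene)
  if (is.na(row)) stop("unknown gene: ", gene)
  as.numeric(strsplit(truth$base_coefficients[row], ";")[[1]])
}

#' Write a simulation truth table as tab-delimited text
#' @param truth truth data frame from [generate_dataset()].
#' @param path output file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
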