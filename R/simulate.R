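#' Simulate negative-binomial count tables with known structure
#'
#' Seeded generator with the statistical structure the analysis verbs
#' assume. Gene-wise mean for sample s:
#' \eqn{\mu_{gs} = \exp(a_g + x_s b_g + z_s c_g) L_s}, with baseline means
#' \eqn{e^{a_g}} lognormal (meanlog log(50), sdlog 1.2), group effects
#' \eqn{b_g = \pm \mathrm{logfc} \cdot \ln 2} for the DE fraction of genes
#' (applied in one non-reference group), gene-specific batch effects
#' \eqn{c_g \sim N(\mathrm{batch\_shift}, \mathrm{batch\_shift}^2)} in log2
#' units (a shift shared by all genes would be a pure depth effect that
#' scaling removes), and per-sample library-size factors \eqn{L_s}
#' lognormal with coefficient of variation `lib_size_cv`. Counts are
#' negative binomial with gene-wise dispersions
#' \eqn{\phi_g \sim} Gamma(shape 2, mean `dispersion_mean`)
#' (variance \eqn{\mu + \phi\mu^2}). Two batches, balanced within groups,
#' are created when `batch_shift != 0`.
#'
#' @param n_samples,n_features Dimensions (samples split evenly over
#'   groups).
#' @param n_groups Number of biological groups (default 2).
#' @param de_fraction Fraction of differentially abundant genes
#'   (default 0.1).
#' @param logfc True absolute log2 fold change of DE genes (default 2).
#' @param batch_shift Batch log2 shift applied to batch 2 (default 0: a
#'   single batch).
#' @param dispersion_mean Mean NB dispersion (default 0.1).
#' @param lib_size_cv Coefficient of variation of library-size factors
#'   (default 0.3).
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline parameters.
#' @param seed Integer seed.
#' @return List with `table` (a validated `tidy_expression_table` with
#'   `group` and `batch` sample annotations) and `truth` (per-feature
#'   baseline log-mean, true log2 FC, target group, dispersion, DE flag;
#'   per-sample library factors as attribute `samples`).
#' @export
simulate_counts <- function(n_samples, n_features, n_groups = 2,
                            de_fraction = 0.1, logfc = 2, batch_shift = 0,
                            dispersion_mean = 0.1, lib_size_cv = 0.3,
                            baseline_meanlog = log(50), baseline_sdlog = 1.2,
                            seed = 1) {
  if (n_samples < 1 || n_features < 1) {
    stop("usage error: dimensions must be positive", call. = FALSE)
  }
  if (de_fraction < 0 || de_fraction > 1) {
    stop("usage error: de_fraction must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  features <- sprintf("G%04d", seq_len(n_features))
  group <- rep_len(paste0("g", seq_len(n_groups)), n_samples)
  group <- group[order(group)]
  batch <- if (batch_shift != 0) {
    b <- integer(n_samples)
    for (gl in unique(group)) {
      idx <- which(group == gl)
      b[idx] <- rep_len(1:2, length(idx))
    }
    paste0("b", b)
  } else {
    rep("b1", n_samples)
  }

  a_g <- stats::rnorm(n_features, baseline_meanlog, baseline_sdlog)
  phi_g <- stats::rgamma(n_features, shape = 2, rate = 2 / dispersion_mean)
  n_de <- round(de_fraction * n_features)
  de_flag <- seq_len(n_features) <= n_de
  de_flag <- sample(de_flag)
  sign_g <- ifelse(stats::runif(n_features) < 0.5, -1, 1)
  target_group <- rep(NA_character_, n_features)
  target_group[de_flag] <- sample(paste0("g", 2:max(2, n_groups)),
                                  sum(de_flag), replace = TRUE)
  b_g <- ifelse(de_flag, sign_g * logfc * log(2), 0)

  sdlog <- sqrt(log(1 + lib_size_cv^2))
  lib_factor <- stats::rlnorm(n_samples, -sdlog^2 / 2, sdlog)
  # gene-specific batch effects (location model): a shift common to all
  # genes would be indistinguishable from sequencing depth and silently
  # removed by scaling, so the spread matches the mean
  c_g <- if (batch_shift != 0) {
    stats::rnorm(n_features, batch_shift, abs(batch_shift)) * log(2)
  } else {
    rep(0, n_features)
  }

  x_mat <- vapply(seq_len(n_samples), function(s) {
    as.numeric(!is.na(target_group) & group[s] == target_group)
  }, numeric(n_features))
  z_s <- as.numeric(batch == "b2")
  mu <- exp(a_g + x_mat * b_g + outer(c_g, z_s)) * rep(lib_factor,
                                                       each = n_features)
  counts <- matrix(
    stats::rnbinom(n_features * n_samples, mu = mu,
                   size = rep(1 / phi_g, n_samples)),
    n_features, n_samples, dimnames = list(features, samples))

  long <- tibble::tibble(
    sample = rep(samples, each = n_features),
    transcript = rep(features, n_samples),
    abundance = as.integer(counts),
    group = rep(group, each = n_features),
    batch = rep(batch, each = n_features))
  table <- tidy_expression_table(long)
  table <- log_method(table, "simulate")
  truth <- tibble::tibble(
    transcript = features, baseline_logmean = a_g, dispersion = phi_g,
    de = de_flag, logfc2 = b_g / log(2), target_group = target_group,
    batch_logfc2 = c_g / log(2))
  attr(truth, "samples") <- tibble::tibble(
    sample = samples, group = group, batch = batch, lib_factor = lib_factor)
  attr(truth, "seed") <- seed
  list(table = table, truth = truth)
}

#' Simulate bulk mixtures from a signature matrix
#'
#' \eqn{y_s = S f_s \times} multiplicative lognormal noise with coefficient
#' of variation `noise_cv` (exact when 0). Fraction rows must lie on the
#' simplex.
#'
#' @param signature Transcript-by-cell-type matrix (or data frame / TSV
#'   path, see [deconvolve_cellularity()]).
#' @param fraction_rows Sample-by-cell-type matrix of true fractions, rows
#'   summing to 1.
#' @param noise_cv Lognormal noise CV (default 0.1).
#' @param seed Integer seed.
#' @return List with `table` (a `tidy_expression_table`) and `fractions`
#'   (the truth, as a tibble).
#' @export
simulate_mixtures <- function(signature, fraction_rows, noise_cv = 0.1,
                              seed = 1) {
  sig <- as_signature_matrix(signature)
  f <- as.matrix(fraction_rows)
  if (is.null(colnames(f))) colnames(f) <- colnames(sig)
  if (any(f < 0) || any(abs(rowSums(f) - 1) > 1e-8)) {
    stop("usage error: fraction rows must lie on the simplex", call. = FALSE)
  }
  if (ncol(f) != ncol(sig)) {
    stop("usage error: fraction columns must match signature cell types",
         call. = FALSE)
  }
  set.seed(seed)
  samples <- rownames(f) %||% sprintf("M%02d", seq_len(nrow(f)))
  y <- sig %*% t(f)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(length(y), -sdlog^2 / 2, sdlog),
                    nrow(y), ncol(y))
    y <- y * noise
  }
  colnames(y) <- samples
  long <- tibble::tibble(
    sample = rep(samples, each = nrow(y)),
    transcript = rep(rownames(sig), ncol(y)),
    abundance = as.numeric(y))
  table <- tidy_expression_table(long)
  table <- log_method(table, "simulate")
  truth <- tibble::as_tibble(f, .name_repair = "minimal")
  truth <- dplyr::mutate(truth, sample = samples, .before = 1)
  list(table = table, fractions = truth)
}

#' Split genes into isoforms to exercise duplicate aggregation
#'
#' For a fraction of features, the counts of each record are partitioned at
#' random (multinomial, Dirichlet-ish gene-wise proportions) across 2-3
#' isoform rows whose counts sum to the original; a `gene_symbol`
#' annotation carries the original feature id for every record, so
#' `aggregate_duplicates(., "gene_symbol")` inverts the split.
#'
#' @param base_table A `tidy_expression_table` with integer counts.
#' @param dup_fraction Fraction of features to split (0 = identity apart
#'   from the added `gene_symbol` column).
#' @param seed Integer seed.
#' @export
simulate_isoform_table <- function(base_table, dup_fraction, seed = 1) {
  stopifnot(is_tidy_expression_table(base_table))
  keys <- te_keys(base_table)
  set.seed(seed)
  features <- unique(as.character(base_table[[keys$transcript]]))
  n_dup <- round(dup_fraction * length(features))
  dup_features <- sample(features, n_dup)
  df <- tibble::as_tibble(base_table)
  df$gene_symbol <- as.character(df[[keys$transcript]])
  if (n_dup == 0) {
    return(restore_te_attributes(df, base_table))
  }
  n_iso <- stats::setNames(sample(2:3, n_dup, replace = TRUE), dup_features)
  probs <- lapply(n_iso, function(k) {
    p <- stats::rgamma(k, shape = 1)
    p / sum(p)
  })
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    g <- df$gene_symbol[i]
    if (!g %in% dup_features) {
      rows[[i]] <- df[i, ]
    } else {
      k <- n_iso[[g]]
      split_counts <- as.integer(stats::rmultinom(1, df[[keys$abundance]][i],
                                                  probs[[g]]))
      block <- df[rep(i, k), ]
      block[[keys$transcript]] <- paste0(g, "_iso", seq_len(k))
      block[[keys$abundance]] <- split_counts
      rows[[i]] <- block
    }
  }
  out <- dplyr::bind_rows(rows)
  res <- restore_te_attributes(out, base_table)
  validate_tidy_expression_table(res)
  res
}
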