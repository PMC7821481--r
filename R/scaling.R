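#' Trimmed mean of M-values scaling factors
#'
#' Native implementation of the TMM scaling-factor estimator. For each
#' sample k against the reference r, gene-wise log-ratios
#' \eqn{M_g = \log_2((y_{gk}/N_k)/(y_{gr}/N_r))}, average log-abundances
#' \eqn{A_g = \tfrac12 \log_2((y_{gk}/N_k)(y_{gr}/N_r))} and inverse
#' asymptotic-variance weights
#' \eqn{w_g = (N_k-y_{gk})/(N_k y_{gk}) + (N_r-y_{gr})/(N_r y_{gr})}
#' are computed over genes with positive counts in both samples; after
#' two-sided trimming of `trim_m` of the M values and `trim_a` of the A
#' values, the factor is \eqn{f_k = 2^{\sum w_g M_g / \sum w_g}}. The
#' reference is the sample whose 75th-percentile CPM is closest to the mean
#' 75th-percentile CPM; factors are rescaled so their geometric mean is 1.
#'
#' @param counts Numeric transcript-by-sample count matrix.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @param lib_sizes Optional library sizes; defaults to column sums. Passing
#'   them explicitly lets factors be estimated on a filtered matrix while
#'   keeping the full-depth library sizes.
#' @return A tibble with columns `sample`, `lib_size`, `tmm_factor`,
#'   `effective_lib_size` (lib_size x factor), `multiplier` (the scale
#'   applied to counts by [scale_abundance()]), and `reference` (logical);
#'   the reference sample id is in attribute `reference_sample`.
#' @export
compute_tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                                lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) {
    stop("domain error: sample(s) with zero library size: ",
         paste(colnames(counts)[lib_sizes <= 0], collapse = ", "),
         call. = FALSE)
  }
  n <- ncol(counts)
  if (n < 2) {
    warning("fewer than 2 samples: all TMM factors set to 1")
    f <- rep(1, n)
    ref <- colnames(counts)[1]
  } else {
    q75 <- vapply(seq_len(n),
                  function(k) stats::quantile(counts[, k] / lib_sizes[k], 0.75),
                  numeric(1))
    ref_idx <- which.min(abs(q75 - mean(q75)))
    ref <- colnames(counts)[ref_idx]
    f <- vapply(seq_len(n), function(k) {
      if (k == ref_idx) return(1)
      tmm_pair_factor(counts[, k], counts[, ref_idx],
                      lib_sizes[k], lib_sizes[ref_idx], trim_m, trim_a)
    }, numeric(1))
    f <- f / geometric_mean(f)
  }
  eff <- lib_sizes * f
  tibble::tibble(
    sample = colnames(counts),
    lib_size = unname(lib_sizes),
    tmm_factor = f,
    effective_lib_size = unname(eff),
    multiplier = geometric_mean(eff) / unname(eff),
    reference = colnames(counts) == ref
  ) |>
    structure(reference_sample = ref)
}

# single-pair TMM factor (unrescaled); genes with a zero in either sample
# are excluded from the M/A set
tmm_pair_factor <- function(y, yr, n, nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (length(y) == 0) return(1)
  p <- y / n; pr <- yr / nr
  m <- log2(p / pr)
  a <- 0.5 * log2(p * pr)
  v <- (n - y) / (n * y) + (nr - yr) / (nr * yr)  # delta-method variance
  if (max(abs(m)) < 1e-6) return(1)  # identical relative profiles
  ng <- length(m)
  lo_m <- floor(ng * trim_m) + 1; hi_m <- ng + 1 - lo_m
  lo_a <- floor(ng * trim_a) + 1; hi_a <- ng + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  # inverse-variance (precision) weighted trimmed mean of M values
  f <- 2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
  if (!is.finite(f)) 1 else f
}

#' Log counts-per-million
#'
#' `log2((y + prior) / (N + 2 * prior) * 1e6)`, the shared transform used by
#' the embedding, variable-selection and voom steps.
#'
#' @param counts Transcript-by-sample matrix.
#' @param lib_sizes Per-sample library sizes (default column sums).
#' @param prior Prior count added to avoid log of zero (default 0.5).
#' @return Matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, lib_sizes = colSums(counts), prior = 0.5) {
  stopifnot(all(lib_sizes > 0))
  t(log2(t(counts + prior) / (lib_sizes + 2 * prior) * 1e6))
}

#' Scale transcript abundance for sequencing depth
#'
#' Adds a `<abundance>_scaled` column:
#' \eqn{\tilde y_{gk} = y_{gk} / (N_k f_k) \times G} where \eqn{N_k f_k} is
#' the effective library size and G the geometric mean of effective library
#' sizes across samples (so scaled counts stay near raw magnitude). Factors
#' are estimated on abundant transcripts only (the `.abundant` flag is
#' computed if absent) and recorded in the internals store.
#'
#' @param x A `tidy_expression_table`.
#' @param method `"tmm"` (default), `"upper_quartile"`, or `"none"`.
#' @param action Action mode; `"add"` (default) returns the full table.
#' @param ... Passed to the factor estimator (e.g. `trim_m`).
#' @return Per the action mode; scaling factors retrievable with
#'   `te_internals(x, "scaling_factors")` or via `action = "get"`.
#' @export
scale_abundance <- function(x, method = c("tmm", "upper_quartile", "none"),
                            action = "add", ...) {
  stopifnot(is_tidy_expression_table(x))
  if (!is.character(method) ||
      !all(method %in% c("tmm", "upper_quartile", "none"))) {
    stop("usage error: unknown scaling method", call. = FALSE)
  }
  method <- match.arg(method)
  keys <- te_keys(x)
  x <- ensure_abundant(x)
  counts <- te_assay(x)
  counts[is.na(counts)] <- 0
  lib_sizes <- colSums(counts)
  flags <- abundant_flags(x)
  abundant_counts <- counts[flags[rownames(counts)], , drop = FALSE]

  sf <- switch(method,
    tmm = compute_tmm_factors(abundant_counts, lib_sizes = lib_sizes, ...),
    upper_quartile = upper_quartile_factors(abundant_counts, lib_sizes),
    none = tibble::tibble(
      sample = colnames(counts), lib_size = unname(lib_sizes),
      tmm_factor = 1, effective_lib_size = unname(lib_sizes),
      multiplier = 1, reference = FALSE)
  )
  mult <- stats::setNames(sf$multiplier, sf$sample)
  scaled_col <- scaled_column(x)
  new_vals <- x[[keys$abundance]] * mult[as.character(x[[keys$sample]])]
  if (method == "none") new_vals <- x[[keys$abundance]]
  out <- x
  out[[scaled_col]] <- unname(new_vals)
  out <- set_internal_slot(out, "scaling_factors", sf)
  out <- log_method(out, if (method == "none") "framework" else method)
  if (action == "add") return(out)
  apply_action(out, sf |> dplyr::rename(!!keys$sample := sample),
               "sample", action)
}

upper_quartile_factors <- function(counts, lib_sizes) {
  f <- vapply(seq_len(ncol(counts)),
              function(k) stats::quantile(counts[, k] / lib_sizes[k], 0.75),
              numeric(1))
  if (any(f <= 0)) stop("domain error: zero upper quartile in a sample",
                        call. = FALSE)
  f <- f / geometric_mean(f)
  eff <- lib_sizes * f
  tibble::tibble(sample = colnames(counts), lib_size = unname(lib_sizes),
                 tmm_factor = unname(f), effective_lib_size = unname(eff),
                 multiplier = geometric_mean(eff) / unname(eff),
                 reference = FALSE)
}

#' Flag abundant transcripts
#'
#' Adds a logical `.abundant` column per transcript using the count-based
#' rule: with CPM cutoff `min_count / median(lib_size) * 1e6` and smallest
#' group size \eqn{n_{min}} (total sample number when no factor is given),
#' the required number of samples is \eqn{n_{min}} when \eqn{n_{min} \le 10}
#' and \eqn{10 + 0.7 (n_{min} - 10)} otherwise; a transcript is abundant
#' when at least that many samples reach the CPM cutoff and its total count
#' is at least `min_total`.
#'
#' @param x A `tidy_expression_table`.
#' @param factor_of_interest Optional sample-wise annotation column used to
#'   take group sizes into account.
#' @param min_count Minimum count per sample, on the scale of a
#'   median-library sample (default 10).
#' @param min_total Minimum total count across samples (default 15).
#' @param action Action mode (element role: transcript).
#' @export
identify_abundant <- function(x, factor_of_interest = NULL, min_count = 10,
                              min_total = 15, action = "add") {
  stopifnot(is_tidy_expression_table(x))
  keys <- te_keys(x)
  counts <- te_assay(x)
  counts[is.na(counts)] <- 0
  lib_sizes <- colSums(counts)
  n <- ncol(counts)
  if (!is.null(factor_of_interest)) {
    if (!factor_of_interest %in% names(x)) {
      stop("schema error: factor column '", factor_of_interest,
           "' not found", call. = FALSE)
    }
    if (!factor_of_interest %in% elementwise_columns(x, "sample")) {
      stop("schema error: factor column '", factor_of_interest,
           "' is not sample-wise", call. = FALSE)
    }
    sframe <- element_frame(x, "sample")
    n_min <- min(table(sframe[[factor_of_interest]]))
  } else {
    n_min <- n
  }
  cutoff <- min_count / stats::median(lib_sizes) * 1e6
  required <- if (n_min <= 10) n_min else 10 + (n_min - 10) * 0.7
  cpm <- t(t(counts) / lib_sizes * 1e6)
  flag <- rowSums(cpm >= cutoff) >= required & rowSums(counts) >= min_total
  new_cols <- tibble::tibble(!!keys$transcript := rownames(counts),
                             .abundant = unname(flag))
  out <- apply_action(x, new_cols, "transcript", "add")
  out <- log_method(out, "abundance_filter")
  if (action == "add") out else apply_action(x, new_cols, "transcript", action)
}

#' Keep abundant transcripts
#'
#' Filters the table to transcripts flagged `.abundant` (computing the flag
#' with [identify_abundant()] if absent). A declared filter: record pairs
#' change, internals are preserved.
#'
#' @inheritParams identify_abundant
#' @param ... Passed to [identify_abundant()] when the flag must be computed.
#' @export
keep_abundant <- function(x, ...) {
  x <- ensure_abundant(x, ...)
  restore_te_attributes(tibble::as_tibble(x)[x$.abundant, , drop = FALSE], x)
}

#' Keep the most variable transcripts
#'
#' Ranks transcripts by the variance of their log-CPM across samples and
#' keeps the `top` most variable; ties are broken lexicographically by
#' transcript id.
#'
#' @param x A `tidy_expression_table`.
#' @param top Number of transcripts to keep (default 500).
#' @export
keep_variable <- function(x, top = 500) {
  stopifnot(is_tidy_expression_table(x))
  if (top < 1) stop("usage error: top must be >= 1", call. = FALSE)
  counts <- te_assay(x)
  counts[is.na(counts)] <- 0
  if (nrow(counts) == 0) stop("usage error: no transcripts", call. = FALSE)
  v <- apply(log_cpm(counts), 1, stats::var)
  ord <- order(-v, rownames(counts))
  keep_ids <- rownames(counts)[ord[seq_len(min(top, length(v)))]]
  keys <- te_keys(x)
  sel <- as.character(x[[keys$transcript]]) %in% keep_ids
  restore_te_attributes(tibble::as_tibble(x)[sel, , drop = FALSE], x)
}
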