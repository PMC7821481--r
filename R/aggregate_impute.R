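#' Aggregate duplicated transcripts
#'
#' Collapses records that share a value of `aggregate_key` (typically a gene
#' symbol shared by several isoforms) into one record per (sample, symbol).
#' Abundance is combined with `aggregator` (sum by default, the natural
#' choice for read counts split across isoforms). The transcript key column
#' takes the aggregate key's value; annotation columns constant within a
#' group are kept, varying ones are concatenated with `","`; a
#' `merged_transcripts` column counts how many records were collapsed.
#'
#' @param x A `tidy_expression_table`.
#' @param aggregate_key Name of the annotation column to aggregate by.
#' @param aggregator `"sum"` or `"median"`.
#' @return A `tidy_expression_table` keyed by the aggregate values.
#' @export
aggregate_duplicates <- function(x, aggregate_key, aggregator = c("sum", "median")) {
  stopifnot(is_tidy_expression_table(x))
  if (!is.character(aggregator) ||
      !all(aggregator %in% c("sum", "median"))) {
    stop("usage error: aggregator must be 'sum' or 'median'", call. = FALSE)
  }
  aggregator <- match.arg(aggregator)
  keys <- te_keys(x)
  if (!aggregate_key %in% names(x)) {
    stop("schema error: aggregate key column '", aggregate_key, "' not found",
         call. = FALSE)
  }
  agg_fun <- if (aggregator == "sum") sum else stats::median
  df <- tibble::as_tibble(x)
  other <- setdiff(names(df), c(keys$sample, keys$transcript, keys$abundance,
                                aggregate_key))
  collapse <- function(v) {
    u <- unique(v)
    if (length(u) == 1L) u else paste(v, collapse = ",")
  }
  out <- df |>
    dplyr::group_by(.data[[keys$sample]], .data[[aggregate_key]]) |>
    dplyr::summarise(
      !!keys$abundance := agg_fun(.data[[keys$abundance]]),
      merged_transcripts = dplyr::n(),
      dplyr::across(dplyr::all_of(other), collapse),
      .groups = "drop"
    )
  out[[keys$transcript]] <- out[[aggregate_key]]
  out <- out[, unique(c(keys$sample, keys$transcript, keys$abundance,
                        aggregate_key, other, "merged_transcripts"))]
  res <- new_tidy_expression_table(out, keys, te_internals(x))
  validate_tidy_expression_table(res)
  res
}

#' Impute abundance for missing sample-transcript pairs
#'
#' Makes the table rectangular (every sample crossed with every transcript).
#' A missing (sample, transcript) pair receives the median of the observed
#' abundances of that transcript among samples in the same group (defined by
#' the sample-wise `grouping` column(s)), rounded half-up to an integer; a
#' transcript unobserved in the entire group falls back to 0. Imputed
#' records are flagged in a logical `imputed` column. Sample-wise and
#' transcript-wise annotations are filled in for imputed records; pair-wise
#' annotations stay `NA`.
#'
#' @param x A `tidy_expression_table`.
#' @param grouping Character vector of sample-wise annotation column(s).
#' @return A rectangular `tidy_expression_table` with an `imputed` column.
#' @export
impute_missing_abundance <- function(x, grouping) {
  stopifnot(is_tidy_expression_table(x))
  keys <- te_keys(x)
  missing_cols <- setdiff(grouping, names(x))
  if (length(missing_cols) > 0) {
    stop("schema error: grouping column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samplewise <- elementwise_columns(x, "sample")
  bad <- setdiff(grouping, samplewise)
  if (length(bad) > 0) {
    stop("schema error: grouping column(s) vary within a sample: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(x)
  sample_frame <- element_frame(x, "sample")
  feature_frame <- element_frame(x, "transcript")
  grp_of_sample <- do.call(paste, c(sample_frame[grouping], sep = "\r"))
  names(grp_of_sample) <- as.character(sample_frame[[keys$sample]])

  grid <- tidyr::expand_grid(
    !!keys$sample := unique(df[[keys$sample]]),
    !!keys$transcript := unique(df[[keys$transcript]])
  )
  full <- dplyr::left_join(
    grid, dplyr::mutate(df, imputed = FALSE),
    by = c(keys$sample, keys$transcript))
  miss <- is.na(full$imputed)
  full$imputed[miss] <- TRUE

  if (any(miss)) {
    obs_grp <- grp_of_sample[as.character(df[[keys$sample]])]
    med <- stats::aggregate(
      df[[keys$abundance]],
      by = list(grp = obs_grp, feature = as.character(df[[keys$transcript]])),
      FUN = stats::median)
    med_key <- paste(med$grp, med$feature, sep = "\r")
    need <- paste(grp_of_sample[as.character(full[[keys$sample]][miss])],
                  as.character(full[[keys$transcript]][miss]), sep = "\r")
    vals <- med$x[match(need, med_key)]
    vals[is.na(vals)] <- 0
    full[[keys$abundance]][miss] <- round_half_up(vals)
    # fill element-wise annotations on imputed rows
    for (cl in setdiff(names(sample_frame), keys$sample)) {
      fillv <- sample_frame[[cl]][match(full[[keys$sample]][miss],
                                        sample_frame[[keys$sample]])]
      full[[cl]][miss] <- fillv
    }
    for (cl in setdiff(names(feature_frame), keys$transcript)) {
      fillv <- feature_frame[[cl]][match(full[[keys$transcript]][miss],
                                         feature_frame[[keys$transcript]])]
      full[[cl]][miss] <- fillv
    }
  }
  res <- new_tidy_expression_table(full, keys, te_internals(x))
  res <- log_method(res, "impute")
  validate_tidy_expression_table(res)
  res
}
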