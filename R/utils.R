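# Internal helpers shared across verbs.

# transcript x sample matrix of `value_col`; missing pairs become `fill`
te_assay <- function(x, value_col = te_keys(x)$abundance, fill = NA_real_) {
  keys <- te_keys(x)
  samples <- unique(as.character(x[[keys$sample]]))
  features <- unique(as.character(x[[keys$transcript]]))
  m <- matrix(fill, nrow = length(features), ncol = length(samples),
              dimnames = list(features, samples))
  m[cbind(match(as.character(x[[keys$transcript]]), features),
          match(as.character(x[[keys$sample]]), samples))] <- x[[value_col]]
  m
}

geometric_mean <- function(x) exp(mean(log(x)))

# half-up rounding (round() is banker's and would bias imputed medians)
round_half_up <- function(x) floor(x + 0.5)

# name of the scaled-abundance column for a table (may not exist yet)
scaled_column <- function(x) paste0(te_keys(x)$abundance, "_scaled")

# ensure scaled abundance exists; returns the (possibly augmented) table
ensure_scaled <- function(x, ...) {
  if (scaled_column(x) %in% names(x)) x else scale_abundance(x, ...)
}

# ensure the .abundant flag exists
ensure_abundant <- function(x, ...) {
  if (".abundant" %in% names(x)) x else identify_abundant(x, ...)
}

# effective library sizes aligned to `samples`; recomputed from counts when
# the internals store does not carry scaling factors (e.g. after a shell
# pipe), which is deterministic and therefore equivalent
effective_lib_sizes <- function(x, samples) {
  sf <- te_internals(x, "scaling_factors")
  if (!is.null(sf) && all(samples %in% sf$sample)) {
    stats::setNames(sf$effective_lib_size, sf$sample)[samples]
  } else {
    x <- ensure_abundant(x)
    counts <- te_assay(x)
    counts[is.na(counts)] <- 0
    flags <- abundant_flags(x)
    sf <- compute_tmm_factors(counts[flags[rownames(counts)], , drop = FALSE],
                              lib_sizes = colSums(counts))
    stats::setNames(sf$effective_lib_size, sf$sample)[samples]
  }
}

abundant_flags <- function(x) {
  tf <- pivot_transcript(x)
  stats::setNames(tf$.abundant, tf[[te_keys(x)$transcript]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
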