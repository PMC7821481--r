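#' Reduced dimensions of transcript abundance
#'
#' Sample-wise embeddings computed on the log-CPM of scaled abundance after
#' restricting to abundant transcripts and the `top` most variable ones.
#'
#' * **PCA** — gene-centered log-CPM, singular value decomposition; sample
#'   coordinates are right singular vectors scaled by singular values;
#'   explained variance per component is stored in internals; the sign of
#'   each component is fixed so its largest-|loading| gene has a positive
#'   loading.
#' * **MDS** — leading log-fold-change distances: for each sample pair,
#'   \eqn{d_{ij} = \sqrt{\mathrm{mean\ of\ squares\ of\ the\ top\ largest}\ |logCPM_i - logCPM_j|}}
#'   gene-wise differences; classical scaling of the distance matrix
#'   (double-centering \eqn{B = -\tfrac12 J D^2 J}, eigendecomposition,
#'   coordinates = eigenvectors scaled by square-root eigenvalues). Negative
#'   eigenvalues are dropped; if fewer than `n_dims` non-negative ones
#'   remain, the returned dimensionality shrinks with a warning.
#' * **tSNE** — delegated to Rtsne on the first 50 principal components,
#'   perplexity 30 by default, seeded.
#'
#' @param x A `tidy_expression_table`.
#' @param method `"PCA"`, `"MDS"` or `"tSNE"`.
#' @param n_dims Number of dimensions (default 3; 2 for tSNE).
#' @param top Number of most-variable transcripts used (default 500).
#' @param seed Integer seed (tSNE).
#' @param log_transform Use log-CPM (default TRUE) rather than linear scale.
#' @param perplexity tSNE perplexity (default 30).
#' @param action Action mode (element role: sample).
#' @param ... Passed to the delegated tSNE backend.
#' @return Table with `Dim1..DimK` columns; diagnostics in internals slot
#'   `"reduced_dims"`.
#' @export
reduce_dimensions <- function(x, method = c("PCA", "MDS", "tSNE"),
                              n_dims = NULL, top = 500, seed = NULL,
                              log_transform = TRUE, perplexity = 30,
                              action = "add", ...) {
  stopifnot(is_tidy_expression_table(x))
  method <- match.arg(method)
  if (is.null(n_dims)) n_dims <- if (method == "tSNE") 2 else 3
  x <- ensure_scaled(x)
  keys <- te_keys(x)
  sub <- keep_variable(keep_abundant(x), top = top)
  m <- te_assay(sub, scaled_column(sub))
  m[is.na(m)] <- 0
  n <- ncol(m)
  if (method != "tSNE" && n_dims >= n) {
    stop("usage error: n_dims must be smaller than the number of samples",
         call. = FALSE)
  }
  em <- if (log_transform) log_cpm(m) else m

  res <- switch(method,
    PCA = pca_embedding(em, n_dims),
    MDS = mds_embedding(em, n_dims, top),
    tSNE = tsne_embedding(em, n_dims, perplexity, seed, ...)
  )
  coords <- res$coords
  colnames(coords) <- paste0("Dim", seq_len(ncol(coords)))
  new_cols <- tibble::as_tibble(coords) |>
    dplyr::mutate(!!keys$sample := rownames(coords), .before = 1)
  out <- apply_action(x, new_cols, "sample", "add")
  out <- set_internal_slot(out, "reduced_dims",
                           c(res["diagnostics"], list(method = method)))
  out <- log_method(out, tolower(method))
  if (action == "add") out else apply_action(x, new_cols, "sample", action)
}

pca_embedding <- function(em, n_dims) {
  centered <- em - rowMeans(em)
  sv <- svd(centered)
  k <- min(n_dims, length(sv$d))
  # reproducible orientation: largest-|loading| gene loads positively
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$u[, j]))
    if (sv$u[i_max, j] < 0) {
      sv$u[, j] <- -sv$u[, j]; sv$v[, j] <- -sv$v[, j]
    }
  }
  coords <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- colnames(em)
  expl <- sv$d^2 / sum(sv$d^2)
  list(coords = coords,
       diagnostics = list(singular_values = sv$d,
                          explained_variance = expl[seq_len(k)],
                          loadings = sv$u[, seq_len(k), drop = FALSE]))
}

# leading log-fold-change distance matrix (top largest |diff| genes per pair)
leading_lfc_distances <- function(em, top) {
  n <- ncol(em)
  topn <- min(top, nrow(em))
  d <- matrix(0, n, n, dimnames = list(colnames(em), colnames(em)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs2 <- sort((em[, i] - em[, j])^2, decreasing = TRUE)[seq_len(topn)]
      d[i, j] <- d[j, i] <- sqrt(mean(diffs2))
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds on the
#' eigenvectors of \eqn{B = -\tfrac12 J D^2 J} scaled by the square roots
#' of the leading non-negative eigenvalues.
#'
#' @param d Symmetric distance matrix.
#' @param n_dims Requested dimensionality.
#' @return List with `coords` (may have fewer columns than requested, with a
#'   warning) and `eigenvalues`.
#' @export
classical_mds <- function(d, n_dims) {
  n <- nrow(d)
  j_mat <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j_mat %*% (d^2) %*% j_mat
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-12)
  k <- min(n_dims, length(pos))
  if (k < n_dims) {
    warning("only ", k, " non-negative MDS eigenvalue(s); returning ", k,
            " dimension(s)")
  }
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k, k)
  rownames(coords) <- rownames(d)
  list(coords = coords, eigenvalues = e$values)
}

mds_embedding <- function(em, n_dims, top) {
  d <- leading_lfc_distances(em, top)
  res <- classical_mds(d, n_dims)
  list(coords = res$coords,
       diagnostics = list(eigenvalues = res$eigenvalues,
                          distance_matrix = d))
}

tsne_embedding <- function(em, n_dims, perplexity, seed, ...) {
  if (!requireNamespace("Rtsne", quietly = TRUE)) {
    stop("usage error: the Rtsne package is required for method = 'tSNE'",
         call. = FALSE)
  }
  n <- ncol(em)
  if (n < 3 * perplexity + 1) {
    stop("usage error: tSNE needs > 3 * perplexity samples (have ", n,
         "); lower the perplexity (e.g. perplexity = ",
         max(1, floor((n - 1) / 3)), ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- Rtsne::Rtsne(t(em), dims = n_dims, perplexity = perplexity,
                      pca = TRUE, initial_dims = min(50, n - 1, nrow(em)),
                      check_duplicates = FALSE, ...)
  coords <- fit$Y
  rownames(coords) <- colnames(em)
  list(coords = coords,
       diagnostics = list(costs = fit$costs, perplexity = perplexity,
                          seed = seed))
}
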