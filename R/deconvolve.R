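#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves \eqn{\min_x \|Ax - b\|^2} subject to \eqn{x \ge 0} by the
#' active-set algorithm: repeatedly move the most negatively-correlated
#' variable from the zero set into the passive set, solving the
#' unconstrained problem on the passive set and stepping back along the
#' feasible segment whenever a passive coefficient would turn negative.
#'
#' @param a Numeric matrix (m x n).
#' @param b Numeric vector (length m).
#' @return List with `x` (solution), `residual` (b - Ax), `passive`
#'   (indices of active predictors).
#' @export
nnls_fit <- function(a, b) {
  a <- as.matrix(a)
  n <- ncol(a)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(a, b - a %*% x)
  tol <- 1e-10 * max(abs(w), 1)
  iter <- 0
  while (any(!passive) && max(w[!passive]) > tol && iter < 30 * n) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      ap <- a[, passive, drop = FALSE]
      s <- numeric(n)
      s[passive] <- solve(crossprod(ap), crossprod(ap, b))
      if (min(s[passive]) > tol) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(a, b - a %*% x)
  }
  list(x = as.numeric(x), residual = as.numeric(b - a %*% x),
       passive = which(passive))
}

#' Estimate cell-type fractions by constrained least squares
#'
#' For each sample, the linear-scale abundance vector over the transcripts
#' shared with the signature is regressed on the signature profiles under a
#' non-negativity constraint (native Lawson-Hanson NNLS), and the solution
#' is renormalized to sum to one. Signature rows and the sample vector are
#' scaled by the signature row standard deviation before fitting, so that
#' high-magnitude transcripts do not dominate while the system stays
#' exactly linear (noiseless mixtures are recovered exactly and fractions
#' are invariant to rescaling of the sample vector). An all-zero solution
#' falls back to uniform fractions with a warning. Per-sample goodness of
#' fit (residual RMSE on the raw scale, correlation between observed and
#' reconstructed abundance) is stored in the internals slot
#' `"deconvolution"`.
#'
#' @param x A `tidy_expression_table`.
#' @param signature Transcript-by-cell-type reference matrix (non-negative,
#'   >= 2 columns, no all-zero column), a data frame whose first column is
#'   the transcript id, or a path to a signature TSV (see
#'   [read_signature()]).
#' @param method `"nnls"` (default) or `"ls_clip"` (unconstrained least
#'   squares with negative coefficients clipped to zero, for comparison).
#' @param min_shared Minimum number of signature transcripts that must be
#'   present in the table (default 20).
#' @param action Action mode (element role: sample).
#' @return Table with one `fraction_<cell_type>` column per cell type.
#' @export
deconvolve_cellularity <- function(x, signature, method = c("nnls", "ls_clip"),
                                   min_shared = 20, action = "add") {
  stopifnot(is_tidy_expression_table(x))
  method <- match.arg(method)
  sig <- as_signature_matrix(signature)
  keys <- te_keys(x)
  value_col <- if (scaled_column(x) %in% names(x)) scaled_column(x) else
    keys$abundance
  m <- te_assay(x, value_col)
  shared <- intersect(rownames(sig), rownames(m))
  if (length(shared) < min_shared) {
    stop("data error: only ", length(shared),
         " signature transcript(s) present in the table (need >= ",
         min_shared, ")", call. = FALSE)
  }
  sig <- sig[shared, , drop = FALSE]
  m <- m[shared, , drop = FALSE]
  m[is.na(m)] <- 0
  row_sd <- apply(sig, 1, stats::sd)
  row_sd[row_sd == 0] <- 1
  sig_s <- sig / row_sd

  fracs <- matrix(NA_real_, ncol(m), ncol(sig),
                  dimnames = list(colnames(m), colnames(sig)))
  diag_rows <- vector("list", ncol(m))
  for (s in seq_len(ncol(m))) {
    y <- m[, s] / row_sd
    coef <- if (method == "nnls") {
      nnls_fit(sig_s, y)$x
    } else {
      pmax(stats::lm.fit(sig_s, y)$coefficients, 0)
    }
    if (sum(coef) <= 0) {
      warning("all-zero solution for sample ", colnames(m)[s],
              "; uniform fractions returned")
      coef <- rep(1, ncol(sig))
    }
    recon <- as.numeric(sig %*% coef)
    diag_rows[[s]] <- tibble::tibble(
      sample = colnames(m)[s],
      rmse = sqrt(mean((m[, s] - recon)^2)),
      correlation = suppressWarnings(stats::cor(m[, s], recon)))
    fracs[s, ] <- coef / sum(coef)
  }
  new_cols <- tibble::as_tibble(fracs, .name_repair = "minimal")
  names(new_cols) <- paste0("fraction_", names(new_cols))
  new_cols <- dplyr::mutate(new_cols, !!keys$sample := rownames(fracs),
                            .before = 1)
  out <- apply_action(x, new_cols, "sample", "add")
  out <- set_internal_slot(out, "deconvolution",
                           list(diagnostics = dplyr::bind_rows(diag_rows),
                                shared_features = shared, method = method))
  out <- log_method(out, "nnls")
  if (action == "add") out else apply_action(x, new_cols, "sample", action)
}

as_signature_matrix <- function(signature) {
  if (is.character(signature) && length(signature) == 1) {
    signature <- read_signature(signature)
  }
  if (is.data.frame(signature)) {
    sig <- as.matrix(signature[, -1, drop = FALSE])
    rownames(sig) <- as.character(signature[[1]])
  } else {
    sig <- as.matrix(signature)
  }
  if (any(sig < 0)) stop("domain error: negative signature entries",
                         call. = FALSE)
  if (ncol(sig) < 2) stop("domain error: signature needs >= 2 cell types",
                          call. = FALSE)
  zero_col <- colSums(sig) == 0
  if (any(zero_col)) {
    stop("domain error: all-zero signature column(s): ",
         paste(colnames(sig)[zero_col], collapse = ", "), call. = FALSE)
  }
  sig
}
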