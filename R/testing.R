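#' Test differential transcript abundance
#'
#' Fits a linear model per transcript and tests the contrast coefficient,
#' restricted to abundant transcripts (`.abundant` computed if absent).
#'
#' The default **voom** engine: (1) log-CPM with prior count 0.5 on
#' effective library sizes; (2) per-gene ordinary least squares on the
#' design; (3) lowess trend (span 0.5) of the square-root residual standard
#' deviation against mean log-count; (4) observation-level precision
#' weights = trend(fitted log-count)^-4, with extrapolation clamped at the
#' trend's range endpoints; (5) per-gene weighted least squares; (6)
#' empirical-Bayes variance moderation: with residual df d and gene
#' variances \eqn{s_g^2}, let \eqn{e_g = \log s_g^2 - \psi(d/2) + \log(d/2)};
#' the prior df solves \eqn{\psi'(d_0/2) = \max(\mathrm{var}(e) - \psi'(d/2), 10^{-8})}
#' by Newton inversion of the trigamma, and
#' \eqn{s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))}; posterior
#' variances \eqn{(d_0 s_0^2 + d s_g^2)/(d_0 + d)} give moderated
#' t-statistics on \eqn{d_0 + d} degrees of freedom.
#'
#' The **nb_lrt** engine fits per-gene negative-binomial log-link GLMs with
#' log effective library sizes as offsets, estimates a common dispersion by
#' golden-section maximization of the summed profile log-likelihood, and
#' tests the contrast by a likelihood-ratio chi-square on 1 df.
#'
#' Both engines adjust p-values by Benjamini-Hochberg over the tested
#' transcripts; non-tested transcripts receive missing statistics; a
#' `significant` flag marks fdr below `significance_threshold`.
#'
#' @param x A `tidy_expression_table`.
#' @param .formula Model formula over sample-wise annotations, e.g.
#'   `~ condition`.
#' @param method `"voom"` (default) or `"nb_lrt"`.
#' @param contrast Coefficient to test: name or index; default the last
#'   design column.
#' @param fdr_method Only `"BH"` is implemented.
#' @param significance_threshold FDR cutoff for the convenience flag
#'   (default 0.05).
#' @param action Action mode (element role: transcript).
#' @return Table with per-transcript `logFC` (log2), `ave_expr` (mean
#'   log-CPM), `statistic`, `p_value`, `fdr`, `significant` and `engine`
#'   columns; the full fit is stored in the internals slot `"de_fit"`.
#' @export
test_differential_abundance <- function(x, .formula,
                                        method = c("voom", "nb_lrt"),
                                        contrast = NULL, fdr_method = "BH",
                                        significance_threshold = 0.05,
                                        action = "add") {
  stopifnot(is_tidy_expression_table(x))
  method <- match.arg(method)
  if (!identical(fdr_method, "BH")) {
    stop("usage error: only BH fdr adjustment is implemented", call. = FALSE)
  }
  keys <- te_keys(x)
  x <- ensure_abundant(x)
  counts <- te_assay(x)
  counts[is.na(counts)] <- 0
  sframe <- element_frame(x, "sample")
  sframe <- sframe[match(colnames(counts), as.character(sframe[[keys$sample]])), ]
  design <- build_design(.formula, sframe)
  contrast_idx <- resolve_contrast(contrast, colnames(design))
  eff_lib <- effective_lib_sizes(x, colnames(counts))

  flags <- abundant_flags(x)[rownames(counts)]
  tested <- counts[flags, , drop = FALSE]
  fit <- if (method == "voom") {
    fit_voom(tested, design, contrast_idx, lib_sizes = eff_lib)
  } else {
    fit_nb_lrt(tested, design, contrast_idx, lib_sizes = eff_lib)
  }
  res <- fit$table
  res$fdr <- adjust_pvalues_bh(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr < significance_threshold
  res$engine <- method
  new_cols <- dplyr::rename(res, !!keys$transcript := feature)
  out <- apply_action(x, new_cols, "transcript", "add")
  out <- set_internal_slot(out, "de_fit", fit$internals)
  out <- log_method(out, method)
  if (action == "add") out else apply_action(x, new_cols, "transcript", action)
}

build_design <- function(.formula, sframe) {
  design <- stats::model.matrix(.formula, data = sframe)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("linear algebra error: rank-deficient design; aliased coefficient(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (nrow(design) - ncol(design) < 1) {
    stop("domain error: no residual degrees of freedom", call. = FALSE)
  }
  design
}

resolve_contrast <- function(contrast, coef_names) {
  if (is.null(contrast)) return(length(coef_names))
  if (is.character(contrast)) {
    idx <- match(contrast, coef_names)
    if (is.na(idx)) stop("usage error: unknown coefficient '", contrast, "'",
                         call. = FALSE)
    return(idx)
  }
  as.integer(contrast)
}

#' Native voom + empirical-Bayes moderated t engine
#'
#' Matrix-level engine behind [test_differential_abundance()]; exported so
#' simulation studies can drive it directly.
#'
#' @param counts Transcript-by-sample count matrix (tested transcripts).
#' @param design Full-rank design matrix (samples x coefficients).
#' @param contrast_idx Column index of the tested coefficient.
#' @param lib_sizes Effective library sizes (default column sums).
#' @param span Lowess span of the mean-variance trend (default 0.5).
#' @return List with `table` (feature, logFC, ave_expr, statistic, p_value)
#'   and `internals` (weights, trend, prior df/variance, posterior
#'   variances).
#' @export
fit_voom <- function(counts, design, contrast_idx, lib_sizes = colSums(counts),
                     span = 0.5) {
  counts <- as.matrix(counts)
  n <- ncol(counts); p <- ncol(design)
  d_resid <- n - p
  if (d_resid < 1) stop("domain error: no residual degrees of freedom",
                        call. = FALSE)
  y <- t(log2(t(counts + 0.5) / (lib_sizes + 1) * 1e6))

  xtxi_xt <- solve(crossprod(design), t(design))
  beta <- y %*% t(xtxi_xt)                      # genes x p
  fitted <- beta %*% t(design)
  resid <- y - fitted
  sigma <- sqrt(rowSums(resid^2) / d_resid)
  amean <- rowMeans(y)

  # mean-variance trend on sqrt-sd vs average log-count
  sx <- amean + mean(log2(lib_sizes + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  lo <- stats::lowess(sx, sy, f = span)
  trend <- stats::approxfun(lo, rule = 2, ties = list("ordered", mean))
  fitted_cpm <- 2^fitted
  fitted_count <- 1e-6 * t(t(fitted_cpm) * (lib_sizes + 1))
  w <- trend(log2(fitted_count))^-4
  dim(w) <- dim(counts)

  wls <- wls_by_gene(y, design, w, contrast_idx)
  s2 <- wls$s2
  eb <- squeeze_variances(s2, d_resid)
  s2_post <- if (is.finite(eb$d0)) {
    (eb$d0 * eb$s0_2 + d_resid * s2) / (eb$d0 + d_resid)
  } else {
    rep(eb$s0_2, length(s2))
  }
  df_total <- min(eb$d0 + d_resid, nrow(counts) * d_resid)
  tstat <- wls$beta_c / sqrt(s2_post * wls$v_c)
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)

  features <- rownames(counts) %||% paste0("feature", seq_len(nrow(counts)))
  list(
    table = tibble::tibble(feature = features, logFC = unname(wls$beta_c),
                           ave_expr = unname(amean), statistic = unname(tstat),
                           p_value = unname(pval)),
    internals = list(weights = w, trend = lo, df_residual = d_resid,
                     df_prior = eb$d0, var_prior = eb$s0_2,
                     var_post = s2_post, sigma = sqrt(s2),
                     stdev_unscaled = sqrt(wls$v_c), design = design,
                     contrast_idx = contrast_idx)
  )
}

# per-gene weighted least squares, vectorized through cross-product maps;
# returns contrast coefficient, its unscaled variance, and residual variance
wls_by_gene <- function(y, design, w, contrast_idx) {
  g <- nrow(y); n <- ncol(y); p <- ncol(design)
  # X'WX entries as genes x (p*p) via matrix products
  xx <- matrix(NA_real_, g, p * p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      v <- w %*% (design[, i] * design[, j])
      xx[, (i - 1) * p + j] <- v
      xx[, (j - 1) * p + i] <- v
    }
  }
  xy <- matrix(NA_real_, g, p)
  wy <- w * y
  for (i in seq_len(p)) xy[, i] <- wy %*% design[, i]
  beta <- matrix(NA_real_, g, p)
  v_c <- numeric(g)
  for (gi in seq_len(g)) {
    xtwx <- matrix(xx[gi, ], p, p)
    xtwx_inv <- solve(xtwx)
    beta[gi, ] <- xtwx_inv %*% xy[gi, ]
    v_c[gi] <- xtwx_inv[contrast_idx, contrast_idx]
  }
  fitted <- beta %*% t(design)
  s2 <- rowSums(w * (y - fitted)^2) / (n - p)
  list(beta = beta, beta_c = beta[, contrast_idx], v_c = v_c, s2 = s2)
}

# EB variance moderation: fit a scaled inverse-chi-square prior to the
# gene-wise variances by matching log-variance moments. When the observed
# log-variance spread does not exceed the chi-square sampling noise there
# is no evidence of gene-wise heterogeneity: the prior df is infinite and
# every variance shrinks fully to the common mean.
squeeze_variances <- function(s2, d) {
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- mean(s2)
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Newton inversion of the trigamma function
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Native negative-binomial likelihood-ratio engine
#'
#' Per-gene NB log-link GLMs with log effective library sizes as offsets.
#' A common dispersion is estimated by golden-section maximization of the
#' profile log-likelihood summed over genes; each gene is then tested by a
#' likelihood-ratio chi-square (1 df) comparing the full design with the
#' design lacking the contrast column.
#'
#' @inheritParams fit_voom
#' @param dispersion_range Search interval for the common dispersion.
#' @export
fit_nb_lrt <- function(counts, design, contrast_idx,
                       lib_sizes = colSums(counts),
                       dispersion_range = c(1e-4, 10)) {
  counts <- as.matrix(counts)
  offsets <- log(lib_sizes)
  phi <- golden_section(
    function(lphi) nb_profile_loglik(counts, design, offsets, exp(lphi)),
    log(dispersion_range[1]), log(dispersion_range[2]))
  phi <- exp(phi)
  reduced <- design[, -contrast_idx, drop = FALSE]
  g <- nrow(counts)
  logfc <- stat <- pval <- numeric(g)
  theta <- 1 / phi
  for (gi in seq_len(g)) {
    full_fit <- nb_glm(counts[gi, ], design, offsets, theta)
    red_fit <- nb_glm(counts[gi, ], reduced, offsets, theta)
    lr <- max(0, 2 * (full_fit$loglik - red_fit$loglik))
    logfc[gi] <- full_fit$coef[contrast_idx] / log(2)
    stat[gi] <- lr
    pval[gi] <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  }
  ave <- rowMeans(log_cpm(counts, lib_sizes))
  features <- rownames(counts) %||% paste0("feature", seq_len(g))
  list(
    table = tibble::tibble(feature = features, logFC = logfc, ave_expr = ave,
                           statistic = stat, p_value = pval),
    internals = list(dispersion = phi, design = design,
                     contrast_idx = contrast_idx)
  )
}

nb_glm <- function(y, design, offsets, theta) {
  fit <- suppressWarnings(stats::glm.fit(
    design, y, offset = offsets,
    family = MASS::negative.binomial(theta = theta)))
  mu <- fit$fitted.values
  list(coef = fit$coefficients,
       loglik = sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE)))
}

nb_profile_loglik <- function(counts, design, offsets, phi) {
  theta <- 1 / phi
  sum(vapply(seq_len(nrow(counts)), function(gi) {
    nb_glm(counts[gi, ], design, offsets, theta)$loglik
  }, numeric(1)))
}

golden_section <- function(f, lo, hi, tol = 1e-4, max_iter = 60) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  for (i in seq_len(max_iter)) {
    if (abs(b - a) < tol) break
    if (fc > fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  (a + b) / 2
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' \eqn{fdr_i = \min_{j \ge rank(i)} (m/j) p_{(j)}}, capped at 1; ties are
#' handled stably and NA p-values propagate.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @export
adjust_pvalues_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("domain error: p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  out
}

#' Identify marker transcripts across class permutations
#'
#' For every ordered pair of classes (A, B), differential abundance is
#' tested on the A-union-B subset with an A-versus-B contrast; transcripts
#' with `logFC > logfc_min` (higher in A) and `fdr < fdr_max` are retained,
#' ranked by decreasing logFC, and the `top_n` best kept per pair. FDR is
#' adjusted within each pair. Classes with a single sample are skipped with
#' a warning.
#'
#' @param x A `tidy_expression_table`.
#' @param class_column Sample-wise annotation naming the classes (e.g. cell
#'   type).
#' @param logfc_min Minimum log2 fold change (default 2).
#' @param fdr_max Maximum FDR (default 0.05).
#' @param top_n Markers kept per ordered pair (default 10).
#' @param method Engine passed to [test_differential_abundance()].
#' @return Tibble (`class_a`, `class_b`, `feature`, `logFC`, `fdr`, `rank`).
#' @export
identify_markers <- function(x, class_column, logfc_min = 2, fdr_max = 0.05,
                             top_n = 10, method = "voom") {
  stopifnot(is_tidy_expression_table(x))
  keys <- te_keys(x)
  sframe <- element_frame(x, "sample")
  if (!class_column %in% names(sframe)) {
    stop("schema error: class column '", class_column,
         "' is not sample-wise", call. = FALSE)
  }
  sizes <- table(sframe[[class_column]])
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("class(es) with a single sample skipped: ",
            paste(small, collapse = ", "))
  }
  classes <- names(sizes)[sizes >= 2]
  if (length(classes) < 2) {
    stop("usage error: need >= 2 classes with >= 2 samples", call. = FALSE)
  }
  pairs <- expand.grid(class_a = classes, class_b = classes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$class_a != pairs$class_b, ]
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$class_a[i]; b <- pairs$class_b[i]
    in_pair <- as.character(x[[class_column]]) %in% c(a, b)
    sub <- restore_te_attributes(tibble::as_tibble(x)[in_pair, , drop = FALSE], x)
    # contrast coded so positive logFC means higher in class A
    sub$.class <- factor(as.character(sub[[class_column]]), levels = c(b, a))
    res <- test_differential_abundance(sub, ~.class, method = method,
                                       action = "only")
    res <- res[!is.na(res$p_value) & res$logFC > logfc_min &
                 res$fdr < fdr_max, ]
    if (nrow(res) == 0) return(NULL)
    res <- res[order(-res$logFC), ][seq_len(min(top_n, nrow(res))), ]
    tibble::tibble(class_a = a, class_b = b,
                   feature = res[[keys$transcript]], logFC = res$logFC,
                   fdr = res$fdr, rank = seq_len(nrow(res)))
  })
  dplyr::bind_rows(out)
}

#' Gene-set over-representation test
#'
#' Hypergeometric upper-tail test of an unranked gene list against each
#' gene set: with universe size N, set size K (after intersecting with the
#' universe), list size n and overlap k, \eqn{p = P(X \ge k)}. FDR by
#' Benjamini-Hochberg across sets.
#'
#' @param gene_list Character vector of selected genes.
#' @param gene_sets Named list of character vectors, or a path to a GMT
#'   file (read with [read_gmt()]).
#' @param universe Character vector of all assayed genes.
#' @return Tibble (`gene_set`, `set_size`, `overlap`, `expected`,
#'   `p_value`, `fdr`).
#' @export
test_gene_overrepresentation <- function(gene_list, gene_sets, universe) {
  if (length(universe) == 0) stop("usage error: empty universe", call. = FALSE)
  if (is.character(gene_sets) && length(gene_sets) == 1) {
    gene_sets <- read_gmt(gene_sets)
  }
  universe <- unique(universe)
  outside <- setdiff(gene_list, universe)
  if (length(outside) > 0) {
    warning(length(outside), " gene(s) outside the universe dropped")
    gene_list <- intersect(gene_list, universe)
  }
  gene_list <- unique(gene_list)
  n <- length(gene_list); big_n <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(gene_list, set))
    m <- length(set)
    p <- stats::phyper(k - 1, m, big_n - m, n, lower.tail = FALSE)
    tibble::tibble(gene_set = nm, set_size = m, overlap = k,
                   expected = n * m / big_n, p_value = p)
  })
  res <- dplyr::bind_rows(rows)
  res$fdr <- adjust_pvalues_bh(res$p_value)
  res
}

#' Test differential tissue composition
#'
#' Per cell type, fractions are clamped to `[eps, 1 - eps]`,
#' logit-transformed, and modeled by ordinary least squares on the formula's
#' design; the contrast (last coefficient by default) is tested two-sided.
#' A cell type with constant response returns coefficient 0 and p = 1.
#' FDR by Benjamini-Hochberg across cell types.
#'
#' @param fractions Data frame with one row per sample: covariate columns
#'   referenced by the formula plus cell-type fraction columns.
#' @param .formula Model formula over the covariate columns.
#' @param fraction_columns Names of the fraction columns; defaults to
#'   columns starting with `"fraction_"`.
#' @param contrast Coefficient to test (default last).
#' @param eps Clamp width on the fraction scale (default 1e-3).
#' @return Tibble (`cell_type`, `coefficient`, `statistic`, `p_value`,
#'   `fdr`).
#' @export
test_differential_cellularity <- function(fractions, .formula,
                                          fraction_columns = NULL,
                                          contrast = NULL, eps = 1e-3) {
  fractions <- tibble::as_tibble(fractions)
  if (is.null(fraction_columns)) {
    fraction_columns <- grep("^fraction_", names(fractions), value = TRUE)
  }
  if (length(fraction_columns) == 0) {
    stop("usage error: no fraction columns found", call. = FALSE)
  }
  bad <- vapply(fraction_columns, function(cl) {
    any(fractions[[cl]] < 0 | fractions[[cl]] > 1)
  }, logical(1))
  if (any(bad)) {
    stop("domain error: fractions outside [0, 1] in: ",
         paste(fraction_columns[bad], collapse = ", "), call. = FALSE)
  }
  design <- build_design(.formula, fractions)
  cidx <- resolve_contrast(contrast, colnames(design))
  rows <- lapply(fraction_columns, function(cl) {
    y <- stats::qlogis(pmin(pmax(fractions[[cl]], eps), 1 - eps))
    if (stats::sd(y) < 1e-12) {
      return(tibble::tibble(cell_type = sub("^fraction_", "", cl),
                            coefficient = 0, statistic = 0, p_value = 1))
    }
    fit <- stats::lm.fit(design, y)
    d <- length(y) - fit$rank
    s2 <- sum(fit$residuals^2) / d
    xtxi <- chol2inv(chol(crossprod(design)))
    se <- sqrt(s2 * xtxi[cidx, cidx])
    tt <- fit$coefficients[cidx] / se
    tibble::tibble(cell_type = sub("^fraction_", "", cl),
                   coefficient = unname(fit$coefficients[cidx]),
                   statistic = unname(tt),
                   p_value = unname(2 * stats::pt(-abs(tt), df = d)))
  })
  res <- dplyr::bind_rows(rows)
  res$fdr <- adjust_pvalues_bh(res$p_value)
  res
}
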