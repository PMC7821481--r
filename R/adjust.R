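#' Remove known unwanted variation from transcript abundance
#'
#' Empirical-Bayes location/scale batch adjustment on the log scale. The
#' formula names the wanted variation first and the unwanted (batch) factor
#' second, e.g. `~ condition + sequencing_run`. On scaled abundance
#' (computed if absent) the pipeline is:
#'
#' 1. \eqn{Y = \log_2(\tilde y + 1)};
#' 2. standardize: least-squares fit of batch means plus wanted covariates;
#'    per-gene grand mean = batch-size-weighted mean of batch means; pooled
#'    variance = mean squared residual; \eqn{Z = (Y - \alpha - X\beta)/\sigma};
#' 3. per gene and batch, location \eqn{\hat\gamma} (batch mean of Z) and
#'    scale \eqn{\hat\delta^2} (batch variance of Z);
#' 4. parametric priors by moments: normal prior on \eqn{\gamma} with mean and
#'    variance of \eqn{\hat\gamma} over genes; inverse-gamma prior on
#'    \eqn{\delta^2} with \eqn{\lambda = (\bar m^2 + 2s)/s},
#'    \eqn{\theta = (\bar m s + \bar m^3)/s} from the mean \eqn{\bar m} and
#'    variance \eqn{s} of \eqn{\hat\delta^2} over genes;
#' 5. iterate the posterior equations
#'    \eqn{\gamma^* = (n_i\tau^2\hat\gamma + \delta^{*2}\bar\gamma)/(n_i\tau^2 + \delta^{*2})},
#'    \eqn{\delta^{*2} = (\theta + \tfrac12\sum_k (Z_{gk}-\gamma^*)^2)/(n_i/2 + \lambda - 1)}
#'    to a sup-norm tolerance;
#' 6. \eqn{Z^* = (Z-\gamma^*)/\delta^*}; \eqn{Y_{adj} = \sigma Z^* + \alpha + X\beta};
#' 7. adjusted count = `round(max(2^Y_adj - 1, 0))`.
#'
#' Wanted covariates are part of the standardization model and restored
#' afterwards, so biological effects are protected. With a single batch the
#' adjustment is the identity on the log scale. The fitted model is stored
#' in the internals slot `"batch_model"`.
#'
#' @param x A `tidy_expression_table`.
#' @param .formula Formula `~ wanted + batch` over sample-wise annotations.
#' @param parametric Only the parametric (moment-matched) priors are
#'   implemented; `FALSE` errors.
#' @param max_iter,tol EB iteration cap and sup-norm tolerance.
#' @param action Action mode.
#' @return Table with `<scaled>_adjusted` (integer) and
#'   `<scaled>_adjusted_log2` (continuous) columns.
#' @export
adjust_abundance <- function(x, .formula, parametric = TRUE,
                             max_iter = 100, tol = 1e-4, action = "add") {
  stopifnot(is_tidy_expression_table(x))
  if (!parametric) {
    stop("usage error: only the parametric empirical-Bayes priors are implemented",
         call. = FALSE)
  }
  vars <- all.vars(.formula)
  if (length(vars) < 2) {
    stop("usage error: formula must name wanted variation then a batch factor",
         call. = FALSE)
  }
  wanted <- vars[-length(vars)]
  batch_col <- vars[length(vars)]
  x <- ensure_scaled(x)
  keys <- te_keys(x)
  sframe <- element_frame(x, "sample")
  missing_cols <- setdiff(c(wanted, batch_col), names(sframe))
  if (length(missing_cols) > 0) {
    stop("schema error: sample-wise column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  scaled <- te_assay(x, scaled_column(x))
  if (anyNA(scaled)) {
    stop("domain error: table is not rectangular; impute_missing_abundance first",
         call. = FALSE)
  }
  sframe <- sframe[match(colnames(scaled), as.character(sframe[[keys$sample]])), ]
  batch <- factor(sframe[[batch_col]])
  y_log <- log2(scaled + 1)

  if (nlevels(batch) < 2) {
    y_adj <- y_log
    model <- list(batches = levels(batch), identity = TRUE)
  } else {
    fit <- eb_batch_adjust(y_log, batch,
                           stats::as.formula(paste("~", paste(wanted, collapse = "+"))),
                           sframe, max_iter, tol)
    y_adj <- fit$adjusted
    model <- fit$model
  }
  adj_counts <- round(pmax(2^y_adj - 1, 0))
  scaled_col <- scaled_column(x)
  long_idx <- cbind(match(as.character(x[[keys$transcript]]), rownames(y_adj)),
                    match(as.character(x[[keys$sample]]), colnames(y_adj)))
  out <- x
  out[[paste0(scaled_col, "_adjusted")]] <- adj_counts[long_idx]
  out[[paste0(scaled_col, "_adjusted_log2")]] <- y_adj[long_idx]
  out <- set_internal_slot(out, "batch_model", model)
  out <- log_method(out, "combat")
  if (action == "add") return(out)
  new_cols <- tibble::as_tibble(out)[
    , c(keys$sample, keys$transcript, paste0(scaled_col, "_adjusted"),
        paste0(scaled_col, "_adjusted_log2"))]
  if (action == "only") return(new_cols)
  stop("usage error: action must be 'add' or 'only' for pair-wise results",
       call. = FALSE)
}

# Core EB location/scale adjustment on a genes x samples log matrix.
eb_batch_adjust <- function(y_log, batch, wanted_formula, sframe,
                            max_iter = 100, tol = 1e-4) {
  n <- ncol(y_log)
  batch_design <- stats::model.matrix(~ 0 + batch)
  n_batch <- nlevels(batch)
  batch_sizes <- colSums(batch_design)
  if (any(batch_sizes < 2)) {
    stop("domain error: batch(es) with fewer than 2 samples: ",
         paste(levels(batch)[batch_sizes < 2], collapse = ", "), call. = FALSE)
  }
  mod <- stats::model.matrix(wanted_formula, data = sframe)
  mod <- mod[, colnames(mod) != "(Intercept)", drop = FALSE]
  design <- cbind(batch_design, mod)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("linear algebra error: design is singular; confounded coefficient(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  b_hat <- solve(crossprod(design), t(design) %*% t(y_log))  # coef x genes
  grand_mean <- crossprod(batch_sizes / n, b_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- rowMeans((y_log - t(design %*% b_hat))^2)
  var_pooled <- pmax(var_pooled, 1e-12)
  stand_mean <- matrix(grand_mean, nrow(y_log), n)
  tmp <- design; tmp[, seq_len(n_batch)] <- 0
  stand_mean <- stand_mean + t(tmp %*% b_hat)
  z <- (y_log - stand_mean) / sqrt(var_pooled)

  gamma_star <- delta_star <- matrix(NA_real_, nrow(y_log), n_batch)
  gamma_hat <- delta_hat <- matrix(NA_real_, nrow(y_log), n_batch)
  priors <- vector("list", n_batch)
  for (i in seq_len(n_batch)) {
    idx <- batch == levels(batch)[i]
    zi <- z[, idx, drop = FALSE]
    ni <- sum(idx)
    g_hat <- rowMeans(zi)
    d_hat <- apply(zi, 1, stats::var)
    gamma_hat[, i] <- g_hat; delta_hat[, i] <- d_hat
    g_bar <- mean(g_hat); t2 <- max(stats::var(g_hat), 1e-12)
    m_bar <- mean(d_hat); s <- stats::var(d_hat)
    if (!is.finite(s) || s < 1e-12) {
      # degenerate scale prior (e.g. noiseless input): no shrinkage target
      lambda <- 1; theta <- 0
    } else {
      lambda <- (m_bar^2 + 2 * s) / s
      theta <- (m_bar * s + m_bar^3) / s
    }
    priors[[i]] <- list(gamma_bar = g_bar, tau2 = t2,
                        lambda = lambda, theta = theta, n = ni)
    g_old <- g_hat; d_old <- pmax(d_hat, 1e-12)
    it <- 0; converged <- FALSE
    while (it < max_iter) {
      it <- it + 1
      g_new <- (ni * t2 * g_hat + d_old * g_bar) / (ni * t2 + d_old)
      sum2 <- rowSums((zi - g_new)^2)
      d_new <- pmax((theta + 0.5 * sum2) / (ni / 2 + lambda - 1), 1e-12)
      if (max(abs(g_new - g_old), abs(d_new - d_old)) < tol) {
        g_old <- g_new; d_old <- d_new; converged <- TRUE; break
      }
      g_old <- g_new; d_old <- d_new
    }
    if (!converged) warning("EB iteration reached max_iter without convergence")
    gamma_star[, i] <- g_old
    delta_star[, i] <- d_old
  }
  z_star <- z
  for (i in seq_len(n_batch)) {
    idx <- batch == levels(batch)[i]
    z_star[, idx] <- (z[, idx, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  adjusted <- z_star * sqrt(var_pooled) + stand_mean
  list(adjusted = adjusted,
       model = list(batches = levels(batch), identity = FALSE,
                    grand_mean = as.numeric(grand_mean),
                    var_pooled = var_pooled, gamma_hat = gamma_hat,
                    delta_hat = delta_hat, gamma_star = gamma_star,
                    delta_star = delta_star, priors = priors))
}
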