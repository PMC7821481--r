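adjusted_log_matrix <- function(tb) {
  col <- "abundance_scaled_adjusted_log2"
  matrix(tb[[col]], nrow = dplyr::n_distinct(tb$transcript),
         dimnames = list(unique(tb$transcript), unique(tb$sample)))
}

test_that("a single batch is the identity on the log scale", {
  sim <- simulate_counts(8, 60, batch_shift = 0, seed = 31)
  tb <- adjust_abundance(scale_abundance(sim$table), ~ group + batch)
  expect_equal(tb$abundance_scaled_adjusted_log2,
               log2(tb$abundance_scaled + 1), tolerance = 1e-12)
  expect_equal(tb$abundance_scaled_adjusted, round(tb$abundance_scaled))
})

test_that("a pure location shift is fully equalized across batches", {
  set.seed(32)
  g <- 40; n <- 8
  base <- exp(rnorm(g, 5, 1))
  counts <- matrix(round(rep(base, n)), g, n,
                   dimnames = list(sprintf("g%02d", 1:g), paste0("s", 1:n)))
  batch <- rep(c("b1", "b2"), each = 4)
  counts[, batch == "b2"] <- round(counts[, batch == "b2"] * 4)  # +2 on log2
  long <- data.frame(sample = rep(colnames(counts), each = g),
                     transcript = rep(rownames(counts), n),
                     abundance = as.integer(counts),
                     grp = rep(rep(c("x", "y"), 2), each = g * 2),
                     batch = rep(batch, each = g))
  tb <- adjust_abundance(scale_abundance(tidy_expression_table(long),
                                         method = "none"),
                         ~ grp + batch)
  y_adj <- adjusted_log_matrix(tb)
  m1 <- rowMeans(y_adj[, batch == "b1"])
  m2 <- rowMeans(y_adj[, batch == "b2"])
  expect_lt(max(abs(m1 - m2)), 1e-6)
})

test_that("standardization matches a per-gene least-squares oracle", {
  set.seed(33)
  g <- 30; n <- 10
  y <- matrix(rnorm(g * n, 6, 1), g, n,
              dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  batch <- factor(rep(c("b1", "b2"), each = 5))
  grp <- factor(rep(c("a", "b"), 5))
  sframe <- data.frame(group = grp, batch = batch)
  fit <- tidyexpr:::eb_batch_adjust(y, batch, ~group, sframe)
  # oracle: per gene, lm on batch means + group; alpha, sigma2, z
  design <- cbind(model.matrix(~ 0 + batch), model.matrix(~grp)[, -1])
  for (gi in c(1, 7, 30)) {
    co <- lm.fit(design, y[gi, ])$coefficients
    alpha <- sum(table(batch) / n * co[1:2])
    resid <- y[gi, ] - design %*% co
    sigma2 <- mean(resid^2)
    stand <- (y[gi, ] - alpha - model.matrix(~grp)[, -1] * co[3]) /
      sqrt(sigma2)
    for (b in 1:2) {
      zi <- stand[batch == levels(batch)[b]]
      expect_equal(fit$model$gamma_hat[gi, b], mean(zi), tolerance = 1e-10)
      expect_equal(fit$model$delta_hat[gi, b], var(zi), tolerance = 1e-10)
    }
  }
})

test_that("EB shrinkage recovers simulated batch locations", {
  set.seed(34)
  g <- 2000; n <- 60
  gamma_true <- rnorm(g, 0, 1)
  delta2 <- 1 / rgamma(g, shape = 10, rate = 3)
  batch <- factor(rep(c("b1", "b2"), each = n / 2))
  grp <- factor(rep(c("a", "b"), n / 2))
  y <- matrix(rnorm(g * n, 7, 1), g, n,
              dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  y[, batch == "b2"] <- y[, batch == "b2"] +
    matrix(rnorm(g * n / 2, gamma_true, sqrt(delta2)), g, n / 2)
  fit <- tidyexpr:::eb_batch_adjust(y, batch, ~group,
                                    data.frame(group = grp, batch = batch))
  recovered <- (fit$model$gamma_star[, 2] - fit$model$gamma_star[, 1]) *
    sqrt(fit$model$var_pooled)
  expect_gt(cor(recovered, gamma_true), 0.95)
})

test_that("adjustment agrees with the sva ComBat reference", {
  skip_if_not_installed("sva")
  set.seed(35)
  g <- 200; n <- 12
  y <- matrix(rnorm(g * n, 6, 1.5), g, n,
              dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  batch <- factor(rep(c("b1", "b2"), each = 6))
  grp <- factor(rep(c("a", "b"), 6))
  y[, batch == "b2"] <- y[, batch == "b2"] + rnorm(g, 1.5, 0.5)
  ours <- tidyexpr:::eb_batch_adjust(y, batch, ~group,
                                     data.frame(group = grp, batch = batch),
                                     max_iter = 5000, tol = 1e-10)
  theirs <- suppressMessages(
    sva::ComBat(y, batch = batch, mod = model.matrix(~grp)))
  expect_lt(max(abs(ours$adjusted - theirs)), 1e-4)
})

test_that("batch sum of squares collapses while the wanted effect survives", {
  sim <- simulate_counts(12, 300, de_fraction = 0.2, logfc = 2,
                         batch_shift = 1.5, seed = 36)
  tb <- scale_abundance(sim$table)
  before <- log2(adjusted_log_input <- te_assay(tb, "abundance_scaled") + 1)
  adj <- adjust_abundance(tb, ~ group + batch)
  after <- adjusted_log_matrix(adj)
  sframe <- pivot_sample(adj)
  batch <- sframe$batch[match(colnames(after), sframe$sample)]
  grp <- sframe$group[match(colnames(after), sframe$sample)]
  ss_batch <- function(m) {
    centered <- m - rowMeans(m)
    sum(sapply(unique(batch), function(b) {
      nb <- sum(batch == b)
      nb * rowMeans(centered[, batch == b, drop = FALSE])^2
    }))
  }
  expect_gt(1 - ss_batch(after) / ss_batch(before), 0.9)

  # spiked group effects preserved within 25% relative error (median)
  de <- sim$truth$transcript[sim$truth$de]
  lfc_after <- rowMeans(after[de, grp == "g2"]) -
    rowMeans(after[de, grp == "g1"])
  rel_err <- abs(abs(lfc_after) - 2) / 2
  expect_lt(median(rel_err), 0.25)
})

test_that("degenerate designs raise informative errors", {
  sim <- simulate_counts(8, 40, batch_shift = 1, seed = 37)
  tb <- scale_abundance(sim$table)
  confounded <- dplyr::mutate(tb, dup = group)
  expect_error(adjust_abundance(confounded, ~ dup + group),
               "singular|confounded")
  tiny <- dplyr::filter(tb, !(sample == "S01"))
  tiny <- dplyr::mutate(tiny, lonely = ifelse(sample == "S02", "a", "b"))
  expect_error(adjust_abundance(tiny, ~ group + lonely), "fewer than 2")
})

test_that("the EB iteration converges on fuzzed inputs", {
  for (seed in 41:44) {
    set.seed(seed)
    g <- 50; n <- 9
    y <- matrix(rnorm(g * n, 5, 2), g, n,
                dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
    batch <- factor(rep(c("b1", "b2", "b3"), each = 3))
    grp <- factor(rep_len(c("a", "b", "c"), n))
    expect_no_warning(
      tidyexpr:::eb_batch_adjust(y, batch, ~group,
                                 data.frame(group = grp, batch = batch)))
  }
})
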