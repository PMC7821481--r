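test_that("a constant transcript has zero logFC and statistic", {
  # equal library sizes by a circulant layout, one flat transcript on top
  g <- 24; n <- 8
  base <- round(exp(seq(log(20), log(2000), length.out = g)))
  counts <- sapply(seq_len(n), function(s) base[(seq_len(g) + s) %% g + 1])
  counts <- rbind(counts, flat = rep(500, n))
  rownames(counts) <- c(sprintf("g%02d", seq_len(g)), "flat")
  colnames(counts) <- sprintf("s%d", seq_len(n))
  expect_equal(length(unique(colSums(counts))), 1)
  long <- data.frame(sample = rep(colnames(counts), each = g + 1),
                     transcript = rep(rownames(counts), n),
                     abundance = as.integer(counts),
                     group = rep(rep(c("a", "b"), each = n / 2),
                                 each = g + 1))
  tb <- tidy_expression_table(long)
  res <- test_differential_abundance(scale_abundance(tb, method = "none"),
                                     ~group, action = "only")
  row <- res[res$transcript == "flat", ]
  expect_equal(row$logFC, 0, tolerance = 1e-10)
  expect_equal(abs(row$statistic), 0, tolerance = 1e-10)
})

test_that("the native voom engine reproduces the limma reference", {
  skip_if_not_installed("limma")
  # heterogeneous gene-wise dispersions put the EB fit in the regular
  # (finite prior df) branch; homogeneous ones in the fully-shrunk branch
  make_counts <- function(seed, het) {
    set.seed(seed)
    size <- if (het) exp(runif(400, log(1), log(50))) else rep(5, 400)
    matrix(rnbinom(400 * 10, mu = exp(rnorm(400 * 10, log(100), 1)),
                   size = size),
           400, 10, dimnames = list(sprintf("g%03d", 1:400),
                                    paste0("s", 1:10)))
  }
  grp <- factor(rep(c("a", "b"), each = 5))
  design <- model.matrix(~grp)
  branches <- logical(2)
  for (het in c(TRUE, FALSE)) {
    counts <- make_counts(11 + het, het)
    lib <- colSums(counts)
    ours <- fit_voom(counts, design, 2, lib_sizes = lib)
    branches[het + 1] <- is.finite(ours$internals$df_prior)
    v <- limma::voom(counts, design, lib.size = lib, span = 0.5)
    ref <- limma::eBayes(limma::lmFit(v, design))
    expect_equal(max(abs(ours$internals$weights - v$weights) / v$weights),
                 0, tolerance = 1e-10)
    expect_equal(ours$table$logFC, unname(ref$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(ours$table$statistic, unname(ref$t[, 2]),
                 tolerance = 1e-10)
    expect_equal(ours$table$p_value, unname(ref$p.value[, 2]),
                 tolerance = 1e-10)
    expect_equal(ours$internals$df_prior, ref$df.prior, tolerance = 1e-6)
  }
  expect_true(any(branches) && !all(branches))  # both branches exercised
})

test_that("with unit weights and no shrinkage the moderated t is the ordinary t", {
  counts <- random_counts(40, 8, seed = 73)
  grp <- factor(rep(c("a", "b"), each = 4))
  design <- model.matrix(~grp)
  y <- t(log2(t(counts + 0.5) / (colSums(counts) + 1) * 1e6))
  w <- matrix(1, nrow(y), ncol(y))
  wls <- tidyexpr:::wls_by_gene(y, design, w, 2)
  t_ours <- wls$beta_c / sqrt(wls$s2 * wls$v_c)
  t_lm <- apply(y, 1, function(row) {
    summary(lm(row ~ grp))$coefficients[2, "t value"]
  })
  expect_equal(t_ours, unname(t_lm), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("voom controls type-I error and recovers spiked effects", {
  set.seed(74)
  rejections <- replicate(60, {
    sim <- simulate_counts(12, 200, de_fraction = 0,
                           seed = sample.int(1e6, 1))
    counts <- tidyexpr:::te_assay(sim$table)
    design <- model.matrix(~group, pivot_sample(sim$table))
    keep <- rowSums(counts >= 5) >= 6
    fit <- fit_voom(counts[keep, ], design, 2)
    mean(fit$table$p_value < 0.05)
  })
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.08)

  sim <- simulate_counts(12, 400, de_fraction = 0.1, logfc = 2, seed = 75)
  res <- test_differential_abundance(scale_abundance(sim$table), ~group,
                                     action = "only")
  merged <- merge(res, sim$truth, by = "transcript")
  strong <- merged[merged$de & merged$baseline_logmean > log(50) &
                     !is.na(merged$logFC), ]
  expect_lt(median(abs(abs(strong$logFC) - 2)), 0.3)
})

test_that("BH adjustment matches hand-computed and reference values", {
  expect_equal(adjust_pvalues_bh(0.2), 0.2)
  expect_equal(adjust_pvalues_bh(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(76)
  p <- runif(200)^2
  expect_equal(adjust_pvalues_bh(p), p.adjust(p, "BH"))
  perm <- sample(200)
  expect_equal(adjust_pvalues_bh(p[perm]), adjust_pvalues_bh(p)[perm])
  expect_true(all(diff(adjust_pvalues_bh(sort(p))) >= 0))
  expect_error(adjust_pvalues_bh(c(0.5, 1.2)), "domain error")
})

test_that("nb_lrt agrees with voom on direction for strong effects", {
  sim <- simulate_counts(10, 150, de_fraction = 0.2, logfc = 2.5, seed = 77)
  tb <- scale_abundance(sim$table)
  v <- test_differential_abundance(tb, ~group, method = "voom",
                                   action = "only")
  n <- test_differential_abundance(tb, ~group, method = "nb_lrt",
                                   action = "only")
  m <- merge(v, n, by = "transcript", suffixes = c("_v", "_n"))
  strong <- m[!is.na(m$logFC_v) & abs(m$logFC_v) >= 2 & m$ave_expr_v > 5, ]
  expect_gt(nrow(strong), 5)
  expect_gt(mean(sign(strong$logFC_v) == sign(strong$logFC_n)), 0.99)
  expect_true(all(n$statistic >= 0, na.rm = TRUE))
})

test_that("the nb_lrt dispersion estimate is in the right neighbourhood", {
  sim <- simulate_counts(12, 120, de_fraction = 0, dispersion_mean = 0.15,
                         seed = 78)
  counts <- tidyexpr:::te_assay(sim$table)
  keep <- rowSums(counts >= 5) >= 6
  design <- model.matrix(~group, pivot_sample(sim$table))
  fit <- fit_nb_lrt(counts[keep, ], design, 2)
  expect_gt(fit$internals$dispersion, 0.02)
  expect_lt(fit$internals$dispersion, 0.8)
})

test_that("rank-deficient designs and missing df are rejected", {
  sim <- simulate_counts(4, 40, seed = 79)
  tb <- dplyr::mutate(sim$table, copy = group)
  expect_error(test_differential_abundance(tb, ~ group + copy),
               "aliased|rank")
  two <- dplyr::filter(sim$table, sample %in% c("S01", "S03"))
  expect_error(test_differential_abundance(two, ~group),
               "residual degrees")
})

test_that("marker identification finds spiked class markers", {
  set.seed(80)
  sim <- simulate_counts(12, 150, n_groups = 3, de_fraction = 0, seed = 80)
  tb <- sim$table
  # spike one transcript 16-fold higher in group g1 only
  marker <- "G0007"
  up <- tb$transcript == marker & tb$group == "g1"
  tb$abundance[tb$transcript == marker] <- rpois(sum(tb$transcript == marker),
                                                 60)
  tb$abundance[up] <- tb$abundance[up] * 16L
  mk <- identify_markers(scale_abundance(tb), "group", logfc_min = 2,
                         fdr_max = 0.05, top_n = 5)
  a_pairs <- mk[mk$class_a == "g1", ]
  expect_setequal(unique(a_pairs$class_b), c("g2", "g3"))
  expect_true(all(marker %in% a_pairs$feature[a_pairs$class_b == "g2"],
                  marker %in% a_pairs$feature[a_pairs$class_b == "g3"]))
  expect_true(all(mk$logFC > 2 & mk$fdr < 0.05))
  # an infinite threshold empties the table
  expect_equal(nrow(identify_markers(scale_abundance(tb), "group",
                                     logfc_min = Inf)), 0)
})

test_that("null classes produce few marker calls", {
  set.seed(81)
  false_pairs <- replicate(10, {
    sim <- simulate_counts(8, 100, n_groups = 2, de_fraction = 0,
                           seed = sample.int(1e6, 1))
    nrow(identify_markers(scale_abundance(sim$table), "group"))
  })
  expect_lt(mean(false_pairs > 0), 0.3)
})

test_that("hypergeometric over-representation matches the closed form", {
  universe <- paste0("u", 1:10)
  sets <- list(hit = universe[1:5], off = universe[6:10])
  res <- test_gene_overrepresentation(universe[1:5], sets, universe)
  expect_equal(res$p_value[res$gene_set == "hit"], 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(res$overlap[res$gene_set == "off"], 0)
  expect_equal(res$p_value[res$gene_set == "off"], 1)

  # enumeration oracle over all C(10,5) draws
  draws <- combn(10, 5)
  k_obs <- 3
  set <- 1:5
  p_enum <- mean(apply(draws, 2, function(d) length(intersect(d, set))) >=
                   k_obs)
  res2 <- test_gene_overrepresentation(universe[c(1, 2, 3, 9, 10)], sets,
                                       universe)
  expect_equal(res2$p_value[res2$gene_set == "hit"], p_enum,
               tolerance = 1e-12)
  expect_warning(test_gene_overrepresentation(c("u1", "alien"), sets,
                                              universe),
                 "outside the universe")
  expect_error(test_gene_overrepresentation("u1", sets, character()),
               "usage error")
})

test_that("differential cellularity detects shifted fractions", {
  set.seed(82)
  n <- 40
  grp <- rep(c("a", "b"), each = n / 2)
  f1 <- pmin(pmax(0.3 + 0.2 * (grp == "b") + rnorm(n, 0, 0.03), 0), 1)
  f2 <- pmin(pmax(0.5 + rnorm(n, 0, 0.03), 0), 1)
  fr <- data.frame(sample = paste0("s", 1:n), group = grp,
                   fraction_tcell = f1, fraction_mono = f2)
  res <- test_differential_cellularity(fr, ~group)
  expect_lt(res$fdr[res$cell_type == "tcell"], 0.05)
  expect_gt(res$p_value[res$cell_type == "mono"], 0.05)
  # constant fractions: coefficient 0, p 1 by convention
  fr$fraction_flat <- 0.25
  res2 <- test_differential_cellularity(fr, ~group)
  expect_equal(res2$coefficient[res2$cell_type == "flat"], 0)
  expect_equal(res2$p_value[res2$cell_type == "flat"], 1)
  # clamping at the boundary
  fr$fraction_zero <- 0
  res3 <- test_differential_cellularity(fr, ~group)
  expect_equal(res3$coefficient[res3$cell_type == "zero"], 0)
  expect_error(test_differential_cellularity(
    data.frame(fraction_x = 1.2, group = "a"), ~group), "domain error")
})
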