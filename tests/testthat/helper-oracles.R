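# Independent oracles used across tests. Each is written directly from the
# defining formulas, separately from the package implementation.

# TMM factors, step by step: M/A/variance, double trimming, precision-
# weighted mean, upper-quartile reference, geometric-mean rescaling.
oracle_tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  q75 <- sapply(seq_len(ncol(counts)),
                function(k) quantile(counts[, k], 0.75) / lib[k])
  ref <- which.min(abs(q75 - mean(q75)))
  f <- sapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    y <- counts[, k]; yr <- counts[, ref]
    ok <- y > 0 & yr > 0
    y <- y[ok]; yr <- yr[ok]
    m <- log2((y / lib[k]) / (yr / lib[ref]))
    a <- 0.5 * log2((y / lib[k]) * (yr / lib[ref]))
    v <- (lib[k] - y) / (lib[k] * y) + (lib[ref] - yr) / (lib[ref] * yr)
    if (max(abs(m)) < 1e-6) return(1)
    ng <- length(m)
    lo_m <- floor(ng * trim_m) + 1
    lo_a <- floor(ng * trim_a) + 1
    keep <- rank(m) >= lo_m & rank(m) <= ng + 1 - lo_m &
      rank(a) >= lo_a & rank(a) <= ng + 1 - lo_a
    2^(weighted.mean(m[keep], 1 / v[keep]))
  })
  f / exp(mean(log(f)))
}

# Procrustes residual after optimal translation/rotation/reflection/scale
procrustes_residual <- function(x, y) {
  x <- scale(x, scale = FALSE); y <- scale(y, scale = FALSE)
  s <- svd(t(y) %*% x)
  rot <- s$v %*% t(s$u)
  sc <- sum(s$d) / sum(y^2)
  sqrt(sum((x - sc * y %*% rot)^2) / sum(x^2))
}

# the paper-shaped four-record example table
table1_records <- function() {
  data.frame(
    sample = c("S1", "S2", "S3", "S4"),
    transcript = "CD3G",
    abundance = c(0L, 100L, 5L, 5240L),
    annotation = c("Treated", "Treated", "Naive", "Naive"))
}

make_table1 <- function() tidy_expression_table(table1_records())

# random annotated long table with sample-wise, transcript-wise and
# pair-wise columns
random_table <- function(n_samples = 5, n_features = 8, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(sample = paste0("s", seq_len(n_samples)),
                      transcript = paste0("t", seq_len(n_features)),
                      stringsAsFactors = FALSE)
  grid$abundance <- rpois(nrow(grid), 50)
  grid$cond <- c("a", "b")[1 + (match(grid$sample, unique(grid$sample)) %% 2)]
  grid$biotype <- sample(c("coding", "lnc"), n_features,
                         replace = TRUE)[match(grid$transcript,
                                               unique(grid$transcript))]
  grid$pairwise <- rnorm(nrow(grid))
  tidy_expression_table(grid)
}

# negative-binomial count matrix for engine-level tests
random_counts <- function(genes = 50, samples = 4, mu_log = log(100),
                          size = 5, seed = 1) {
  set.seed(seed)
  matrix(rnbinom(genes * samples, mu = exp(rnorm(genes * samples, mu_log, 1)),
                 size = size),
         genes, samples,
         dimnames = list(sprintf("g%03d", 1:genes), paste0("s", 1:samples)))
}
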