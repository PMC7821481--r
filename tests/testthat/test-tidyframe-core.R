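test_that("table creation validates keys, duplicates and sign", {
  tb <- make_table1()
  expect_s3_class(tb, "tidy_expression_table")
  expect_equal(nrow(tb), 4)
  expect_equal(dplyr::n_distinct(tb$sample), 4)
  expect_equal(dplyr::n_distinct(tb$transcript), 1)
  expect_equal(tb$abundance[tb$sample == "S4"], 5240L)

  empty <- tidy_expression_table(
    data.frame(sample = character(), transcript = character(),
               abundance = integer()))
  expect_equal(nrow(empty), 0)

  dup <- rbind(table1_records(), table1_records()[1, ])
  expect_error(tidy_expression_table(dup), "integrity error.*S1.*CD3G")
  neg <- table1_records(); neg$abundance[2] <- -1L
  expect_error(tidy_expression_table(neg), "domain error")
  expect_error(tidy_expression_table(table1_records(), abundance = "nope"),
               "schema error")
})

test_that("pivots keep exactly the element-constant columns", {
  tb <- make_table1()
  ps <- pivot_sample(tb)
  expect_equal(nrow(ps), 4)
  expect_setequal(names(ps), c("sample", "annotation"))
  expect_equal(ps$annotation[ps$sample == "S4"], "Naive")
  pt <- pivot_transcript(tb)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$transcript, "CD3G")

  one <- tidy_expression_table(table1_records()[1, , drop = FALSE])
  expect_equal(nrow(pivot_sample(one)), 1)
})

test_that("pivots agree with a brute-force group-by oracle", {
  for (seed in 1:5) {
    tb <- random_table(seed = seed)
    for (role in c("sample", "transcript")) {
      id <- te_keys(tb)[[role]]
      fr <- if (role == "sample") pivot_sample(tb) else pivot_transcript(tb)
      # oracle: keep columns with one distinct value in every id group
      df <- as.data.frame(tb)
      candidates <- setdiff(names(df), c("sample", "transcript", "abundance"))
      keep <- candidates[sapply(candidates, function(cl) {
        all(tapply(df[[cl]], df[[id]], function(v) length(unique(v))) == 1)
      })]
      expected <- unique(df[, c(id, keep), drop = FALSE])
      expect_setequal(names(fr), c(id, keep))
      expect_equal(nrow(fr), nrow(expected))
    }
  }
})

test_that("action modes honour the add/get/only contracts", {
  tb <- make_table1()
  newc <- data.frame(sample = c("S1", "S2", "S3", "S4"), tmm = c(1, 2, 3, 4))
  added <- apply_action(tb, newc, "sample", "add")
  expect_s3_class(added, "tidy_expression_table")
  expect_equal(nrow(added), nrow(tb))
  expect_true("tmm" %in% names(added))
  got <- apply_action(tb, newc, "sample", "get")
  expect_equal(nrow(got), nrow(pivot_sample(tb)))
  only <- apply_action(tb, newc, "sample", "only")
  expect_equal(names(only), c("sample", "tmm"))
  expect_error(apply_action(tb, data.frame(sample = "S9", tmm = 1),
                            "sample", "add"),
               "join error.*S9")
})

test_that("internals survive dplyr filtering and column addition", {
  sim <- simulate_counts(6, 40, seed = 2)
  tb <- scale_abundance(sim$table)
  filtered <- dplyr::filter(tb, group == "g1")
  expect_s3_class(filtered, "tidy_expression_table")
  expect_false(is.null(te_internals(filtered, "scaling_factors")))
  expect_true("tmm" %in% te_internals(filtered)$log)
  mutated <- dplyr::mutate(tb, extra = 1)
  expect_identical(te_internals(mutated)$log, te_internals(tb)$log)
  sliced <- tb[1:10, ]
  expect_s3_class(sliced, "tidy_expression_table")
  expect_identical(te_keys(sliced), te_keys(tb))
})

test_that("bibliography is deduplicated and invocation ordered", {
  tb <- make_table1()
  expect_length(get_bibliography(tb), 1)
  sim <- simulate_counts(6, 60, seed = 3)
  tb2 <- test_differential_abundance(scale_abundance(sim$table), ~group)
  bib <- get_bibliography(tb2)
  tmm_pos <- grep("scaling normalization", bib)
  voom_pos <- grep("precision weights", bib)
  expect_length(tmm_pos, 1)
  expect_length(voom_pos, 1)
  expect_lt(tmm_pos, voom_pos)
  # scaling twice does not duplicate the citation
  expect_equal(anyDuplicated(get_bibliography(scale_abundance(tb2))), 0)
})

test_that("add-mode verbs are endomorphic on fuzzed tables", {
  for (seed in 1:5) {
    sim <- simulate_counts(6, 50, seed = seed)
    tb <- sim$table
    pairs <- paste(tb$sample, tb$transcript)
    out <- scale_abundance(tb)
    out <- identify_abundant(out)
    out <- test_differential_abundance(out, ~group)
    expect_s3_class(out, "tidy_expression_table")
    expect_identical(paste(out$sample, out$transcript), pairs)
    expect_silent(validate_tidy_expression_table(out))
  }
})

test_that("aggregate_duplicates sums isoforms and is idempotent without them", {
  iso <- tidy_expression_table(data.frame(
    sample = "S", transcript = c("T1", "T2"), abundance = c(3L, 5L),
    gene = "G"))
  agg <- aggregate_duplicates(iso, "gene")
  expect_equal(nrow(agg), 1)
  expect_equal(agg$transcript, "G")
  expect_equal(agg$abundance, 8)
  expect_equal(agg$merged_transcripts, 2)

  tb <- make_table1()
  tb$gene <- tb$transcript
  agg2 <- aggregate_duplicates(tb, "gene")
  expect_equal(sort(agg2$abundance), sort(tb$abundance))
  expect_true(all(agg2$merged_transcripts == 1))
  expect_error(aggregate_duplicates(tb, "gene", aggregator = "max"),
               "usage error")
})

test_that("aggregation matches a brute-force group-by-sum oracle", {
  base <- simulate_counts(5, 30, seed = 9)$table
  iso <- simulate_isoform_table(base, dup_fraction = 0.4, seed = 9)
  agg <- aggregate_duplicates(iso, "gene_symbol")
  oracle <- stats::aggregate(abundance ~ sample + gene_symbol,
                             data = as.data.frame(iso), FUN = sum)
  merged <- merge(as.data.frame(agg), oracle,
                  by = c("sample", "gene_symbol"))
  expect_equal(merged$abundance.x, merged$abundance.y)
  # varying annotations are comma-joined
  multi <- agg$merged_transcripts > 1
  expect_true(all(grepl(",", agg$transcript[multi]) == FALSE))
})

test_that("imputation fills group medians, zero fallback, and flags rows", {
  df <- data.frame(
    sample = c("A1", "A2", "A3", "A4", "A1"),
    transcript = c("g1", "g1", "g1", "other", "only_a1"),
    abundance = c(10L, 20L, 30L, 7L, 2L),
    grp = c("x", "x", "x", "x", "x"))
  tb <- tidy_expression_table(df)
  imp <- impute_missing_abundance(tb, "grp")
  expect_equal(nrow(imp), 4 * 3)  # rectangular
  g1_a4 <- imp$abundance[imp$sample == "A4" & imp$transcript == "g1"]
  expect_equal(g1_a4, 20)  # median of 10, 20, 30
  expect_true(imp$imputed[imp$sample == "A4" & imp$transcript == "g1"])
  expect_false(any(imp$imputed[imp$sample == "A1" & imp$transcript == "g1"]))

  # two groups: transcript absent from a whole group falls back to 0
  df2 <- rbind(df, data.frame(sample = "B1", transcript = "g1",
                              abundance = 99L, grp = "y"))
  imp2 <- impute_missing_abundance(tidy_expression_table(df2), "grp")
  expect_equal(imp2$abundance[imp2$sample == "B1" &
                                imp2$transcript == "only_a1"], 0)
  # non-missing values unchanged
  expect_equal(imp2$abundance[imp2$sample == "A2" & imp2$transcript == "g1"],
               20)
  expect_error(impute_missing_abundance(tb, "transcript"), "schema error")
})

test_that("imputation matches a per-group median oracle on random tables", {
  set.seed(4)
  full <- simulate_counts(8, 25, seed = 4)$table
  drop <- sample(nrow(full), 40)
  sparse <- restore <- full[-drop, ]
  imp <- impute_missing_abundance(sparse, "group")
  expect_equal(nrow(imp),
               dplyr::n_distinct(full$sample) *
                 dplyr::n_distinct(full$transcript))
  obs <- as.data.frame(sparse)
  for (i in which(imp$imputed)[1:10]) {
    s <- imp$sample[i]; tr <- imp$transcript[i]
    g <- unique(obs$group[obs$sample == s])
    vals <- obs$abundance[obs$transcript == tr &
                            obs$group == g]
    expected <- if (length(vals) == 0) 0 else floor(median(vals) + 0.5)
    expect_equal(imp$abundance[i], expected)
  }
  kept <- merge(as.data.frame(sparse), as.data.frame(imp),
                by = c("sample", "transcript"))
  expect_equal(kept$abundance.x, kept$abundance.y)
})
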