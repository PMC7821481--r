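#' Create a tidy expression table
#'
#' The central data structure of the package: a long-format tibble with one
#' record per (sample, transcript) pair, a registered triplet of key columns
#' (sample id, transcript id, abundance) and an out-of-sight internals store
#' that carries scaling factors, fitted models and the invocation log used to
#' assemble a workflow bibliography. Any number of additional annotation
#' columns (sample-wise, transcript-wise or pair-wise) may be present.
#'
#' Validation enforces the type invariants: each (sample, transcript) pair
#' occurs at most once, raw abundance is a non-negative number, and the key
#' names resolve to existing columns. The internals store travels by value:
#' filtering rows or adding columns with dplyr/tidyr verbs preserves it.
#'
#' @param data A data frame in long format.
#' @param sample,transcript,abundance Names of the key columns (strings).
#' @return A `tidy_expression_table` (a tibble subclass).
#' @examples
#' tb <- tidy_expression_table(
#'   data.frame(sample = c("S1", "S2"), transcript = "CD3G",
#'              abundance = c(0L, 100L), condition = "Treated"),
#'   sample = "sample", transcript = "transcript", abundance = "abundance")
#' @export
tidy_expression_table <- function(data, sample = "sample",
                                  transcript = "transcript",
                                  abundance = "abundance") {
  data <- tibble::as_tibble(data)
  keys <- list(sample = sample, transcript = transcript, abundance = abundance)
  missing_keys <- setdiff(unlist(keys), names(data))
  if (length(missing_keys) > 0) {
    stop("schema error: key column(s) not found: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  ab <- data[[abundance]]
  if (!is.numeric(ab)) {
    ab2 <- suppressWarnings(as.numeric(as.character(ab)))
    if (anyNA(ab2) && !all(is.na(ab))) {
      stop("domain error: abundance column '", abundance,
           "' does not parse as numeric", call. = FALSE)
    }
    data[[abundance]] <- ab2
  }
  x <- new_tidy_expression_table(data, keys, internals = list(log = "framework"))
  validate_tidy_expression_table(x)
  x
}

new_tidy_expression_table <- function(data, keys, internals) {
  structure(
    tibble::as_tibble(data),
    keys = keys,
    internals = internals,
    class = c("tidy_expression_table", class(tibble::tibble()))
  )
}

#' Validate a tidy expression table
#'
#' Checks the structural invariants: registered keys resolve, no duplicated
#' (sample, transcript) pair, and non-negative abundance.
#'
#' @param x A `tidy_expression_table`.
#' @return `x`, invisibly, or an error.
#' @export
validate_tidy_expression_table <- function(x) {
  keys <- te_keys(x)
  missing_keys <- setdiff(unlist(keys), names(x))
  if (length(missing_keys) > 0) {
    stop("schema error: key column(s) not found: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  ab <- x[[keys$abundance]]
  if (any(!is.na(ab) & ab < 0)) {
    stop("domain error: negative abundance values present", call. = FALSE)
  }
  pair <- paste(x[[keys$sample]], x[[keys$transcript]], sep = "\r")
  dup <- anyDuplicated(pair)
  if (dup > 0) {
    stop("integrity error: duplicated (sample, transcript) pair: (",
         x[[keys$sample]][dup], ", ", x[[keys$transcript]][dup], ")",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
is_tidy_expression_table <- function(x) inherits(x, "tidy_expression_table")

# ---- key / internals accessors ------------------------------------------

#' Key column registry of a tidy expression table
#' @param x A `tidy_expression_table`.
#' @return Named list with entries `sample`, `transcript`, `abundance`.
#' @export
te_keys <- function(x) attr(x, "keys", exact = TRUE)

#' Internals store of a tidy expression table
#'
#' A named list carried out of sight on the table (by value) holding raw
#' backend results: scaling factors, batch model, embedding diagnostics,
#' fit objects, and the ordered invocation log.
#' @param x A `tidy_expression_table`.
#' @param slot Optional slot name; if given, return that payload only.
#' @export
te_internals <- function(x, slot = NULL) {
  internals <- attr(x, "internals", exact = TRUE)
  if (is.null(internals)) internals <- list(log = character())
  if (is.null(slot)) internals else internals[[slot]]
}

set_internals <- function(x, internals) {
  attr(x, "internals") <- internals
  x
}

set_internal_slot <- function(x, slot, value) {
  internals <- te_internals(x)
  internals[[slot]] <- value
  set_internals(x, internals)
}

log_method <- function(x, tag) {
  internals <- te_internals(x)
  internals$log <- c(internals$log, tag)
  set_internals(x, internals)
}

# ---- attribute preservation under subsetting / dplyr ---------------------

#' @export
`[.tidy_expression_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) out <- restore_te_attributes(out, x)
  out
}

restore_te_attributes <- function(out, template) {
  keys <- te_keys(template)
  # degrade gracefully to a plain tibble if a key column was dropped
  if (!all(unlist(keys) %in% names(out))) {
    class(out) <- setdiff(class(out), "tidy_expression_table")
    return(out)
  }
  new_tidy_expression_table(out, keys, te_internals(template))
}

# dplyr generics: keep class, keys and internals across mutate/filter/...
#' @importFrom dplyr dplyr_reconstruct
#' @export
dplyr_reconstruct.tidy_expression_table <- function(data, template) {
  restore_te_attributes(tibble::as_tibble(data), template)
}

#' @export
print.tidy_expression_table <- function(x, ...) {
  keys <- te_keys(x)
  cat(sprintf(
    "# tidy expression table: %d records | %d samples x %d transcripts\n",
    nrow(x), dplyr::n_distinct(x[[keys$sample]]),
    dplyr::n_distinct(x[[keys$transcript]])))
  cat(sprintf("# keys: sample=%s transcript=%s abundance=%s\n",
              keys$sample, keys$transcript, keys$abundance))
  NextMethod()
  invisible(x)
}

# ---- element-wise column classification ----------------------------------

# A column is element-wise (sample-wise / transcript-wise) iff it takes a
# single distinct value within every element group. Computed on demand; no
# schema declaration needed.
elementwise_columns <- function(x, role = c("sample", "transcript")) {
  role <- match.arg(role)
  keys <- te_keys(x)
  id_col <- keys[[role]]
  other_id <- keys[[setdiff(c("sample", "transcript"), role)]]
  candidates <- setdiff(names(x), c(id_col, other_id, keys$abundance))
  if (length(candidates) == 0 || nrow(x) == 0) return(character())
  grp <- x[[id_col]]
  keep <- vapply(candidates, function(cl) {
    v <- x[[cl]]
    all(vapply(split(v, grp), function(g) length(unique(g)) == 1L, logical(1)))
  }, logical(1))
  candidates[keep]
}

element_frame <- function(x, role = c("sample", "transcript")) {
  role <- match.arg(role)
  keys <- te_keys(x)
  id_col <- keys[[role]]
  cols <- c(id_col, elementwise_columns(x, role))
  out <- dplyr::distinct(tibble::as_tibble(x)[, cols, drop = FALSE])
  class(out) <- class(tibble::tibble())
  out
}

#' Extract non-redundant sample-wise information
#'
#' Returns one row per sample, keeping only the columns that are constant
#' within each sample (sample-wise annotations plus any per-sample results
#' added by verbs). Transcript-wise and pair-wise columns are dropped; a
#' column varying within any sample is silently classified as
#' non-sample-wise.
#'
#' @param x A `tidy_expression_table`.
#' @return A plain tibble, one row per sample.
#' @export
pivot_sample <- function(x) {
  stopifnot(is_tidy_expression_table(x))
  element_frame(x, "sample")
}

#' Extract non-redundant transcript-wise information
#'
#' Mirror of [pivot_sample()] with the roles swapped: one row per transcript,
#' keeping the columns constant within each transcript.
#'
#' @param x A `tidy_expression_table`.
#' @return A plain tibble, one row per transcript.
#' @export
pivot_transcript <- function(x) {
  stopifnot(is_tidy_expression_table(x))
  element_frame(x, "transcript")
}

# ---- action modes --------------------------------------------------------

#' Apply an action mode to newly computed element-wise columns
#'
#' Implements the add/get/only contract shared by every verb. `add` joins the
#' new columns onto the full table (row count unchanged) and returns a tidy
#' expression table; `get` returns a plain element-wise frame (the pivot of
#' the table) with the new columns joined; `only` returns the new columns
#' keyed by element id.
#'
#' @param x A `tidy_expression_table`.
#' @param new_columns A data frame keyed by element id (first join on the
#'   registered sample or transcript key column).
#' @param element_role `"sample"` or `"transcript"`.
#' @param action `"add"`, `"get"` or `"only"`.
#' @return Per the action contract.
#' @export
apply_action <- function(x, new_columns, element_role = c("sample", "transcript"),
                         action = c("add", "get", "only")) {
  element_role <- match.arg(element_role)
  action <- match.arg(action)
  keys <- te_keys(x)
  id_col <- keys[[element_role]]
  new_columns <- tibble::as_tibble(new_columns)
  if (!id_col %in% names(new_columns)) {
    stop("join error: new columns are not keyed by '", id_col, "'",
         call. = FALSE)
  }
  unknown <- setdiff(new_columns[[id_col]], x[[id_col]])
  if (length(unknown) > 0) {
    stop("join error: unknown ", element_role, " id(s) in new columns: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  switch(action,
    add = {
      joined <- dplyr::left_join(tibble::as_tibble(x), new_columns, by = id_col)
      stopifnot(nrow(joined) == nrow(x))
      restore_te_attributes(joined, x)
    },
    get = dplyr::left_join(element_frame(x, element_role), new_columns,
                           by = id_col),
    only = new_columns
  )
}

# ---- bibliography --------------------------------------------------------

#' Extract the bibliography of a workflow
#'
#' Every verb appends a method tag to the invocation log held in the
#' internals store. This returns the corresponding citations, deduplicated,
#' in invocation order; a fresh table yields the framework citation only.
#'
#' @param x A `tidy_expression_table`.
#' @return Character vector of citations.
#' @export
get_bibliography <- function(x) {
  tags <- unique(c("framework", te_internals(x)$log))
  unname(method_citations()[tags])
}

method_citations <- function() {
  c(
    framework = "tidyexpr: a tidy grammar for bulk transcript abundance analysis.",
    tmm = "Robinson MD, Oshlack A (2010). A scaling normalization method for differential expression analysis of RNA-seq data. Genome Biology 11, R25.",
    upper_quartile = "Bullard JH et al. (2010). Evaluation of statistical methods for normalization and differential expression in mRNA-Seq experiments. BMC Bioinformatics 11, 94.",
    abundance_filter = "Chen Y, Lun ATL, Smyth GK (2016). From reads to genes to pathways: differential expression analysis of RNA-Seq experiments. F1000Research 5, 1438.",
    combat = "Johnson WE, Li C, Rabinovic A (2007). Adjusting batch effects in microarray expression data using empirical Bayes methods. Biostatistics 8, 118-127.",
    mds = "Ritchie ME et al. (2015). limma powers differential expression analyses for RNA-sequencing and microarray studies. Nucleic Acids Research 43, e47.",
    pca = "Pearson K (1901). On lines and planes of closest fit to systems of points in space. Philosophical Magazine 2, 559-572.",
    tsne = "van der Maaten L, Hinton G (2008). Visualizing data using t-SNE. Journal of Machine Learning Research 9, 2579-2605.",
    kmeans = "Arthur D, Vassilvitskii S (2007). k-means++: the advantages of careful seeding. SODA 2007, 1027-1035.",
    snn = "Blondel VD et al. (2008). Fast unfolding of communities in large networks. Journal of Statistical Mechanics, P10008.",
    voom = "Law CW, Chen Y, Shi W, Smyth GK (2014). voom: precision weights unlock linear model analysis tools for RNA-seq read counts. Genome Biology 15, R29.",
    nb_lrt = "McCullagh P, Nelder JA (1989). Generalized Linear Models, 2nd edition. Chapman and Hall.",
    bh = "Benjamini Y, Hochberg Y (1995). Controlling the false discovery rate: a practical and powerful approach to multiple testing. JRSS-B 57, 289-300.",
    hypergeometric = "Fisher RA (1935). The logic of inductive inference. JRSS 98, 39-82.",
    nnls = "Lawson CL, Hanson RJ (1974). Solving Least Squares Problems. Prentice-Hall.",
    redundancy = "tidyexpr: greedy correlation/embedding redundancy removal.",
    impute = "tidyexpr: group-wise median imputation of missing abundance.",
    simulate = "tidyexpr: seeded negative-binomial count and mixture simulators."
  )
}
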