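#' Read an expression table from disk
#'
#' Three dialects:
#' * `long` — delimited table (TSV by default, gzip by extension) with
#'   header; key columns named by `sample`, `transcript`, `abundance`.
#' * `wide` — first column transcript ids, remaining columns one per
#'   sample.
#' * `mtx` — MatrixMarket triplet file with one-id-per-line `features` and
#'   `samples` sidecar files; implicit zeros are materialized only when
#'   `dense = TRUE`, otherwise the record count equals the number of
#'   stored entries.
#'
#' @param path Input file ( `"-"` for standard input in the CLI).
#' @param format `"long"`, `"wide"` or `"mtx"`.
#' @param sample,transcript,abundance Key column names (long format).
#' @param delimiter Field delimiter (default tab).
#' @param features,samples Sidecar paths (mtx format); default
#'   `<path>.features` / `<path>.samples`.
#' @param dense Materialize implicit zeros (mtx format; default FALSE).
#' @return A validated `tidy_expression_table`.
#' @export
read_table <- function(path, format = c("long", "wide", "mtx"),
                       sample = "sample", transcript = "transcript",
                       abundance = "abundance", delimiter = "\t",
                       features = NULL, samples = NULL, dense = FALSE) {
  format <- match.arg(format)
  if (format != "mtx" && is.character(path) && !identical(path, "-") &&
      !file.exists(path)) {
    stop("data error: input file not found: ", path, call. = FALSE)
  }
  switch(format,
    long = {
      df <- read_delim_exact(path, delimiter)
      tidy_expression_table(df, sample = sample, transcript = transcript,
                            abundance = abundance)
    },
    wide = {
      df <- read_delim_exact(path, delimiter)
      long <- tidyr::pivot_longer(df, -1, names_to = sample,
                                  values_to = abundance)
      names(long)[1] <- transcript
      long <- long[, c(sample, transcript, abundance)]
      tidy_expression_table(long, sample = sample, transcript = transcript,
                            abundance = abundance)
    },
    mtx = {
      if (!file.exists(path)) {
        stop("data error: input file not found: ", path, call. = FALSE)
      }
      features <- features %||% paste0(path, ".features")
      samples <- samples %||% paste0(path, ".samples")
      for (p in c(features, samples)) {
        if (!file.exists(p)) {
          stop("data error: sidecar file not found: ", p, call. = FALSE)
        }
      }
      m <- methods::as(Matrix::readMM(path), "TsparseMatrix")
      feat_ids <- readr::read_lines(features)
      samp_ids <- readr::read_lines(samples)
      if (nrow(m) != length(feat_ids) || ncol(m) != length(samp_ids)) {
        stop("data error: sidecar lengths do not match matrix dimensions",
             call. = FALSE)
      }
      if (dense) {
        dm <- as.matrix(m)
        long <- tibble::tibble(
          !!sample := rep(samp_ids, each = nrow(dm)),
          !!transcript := rep(feat_ids, ncol(dm)),
          !!abundance := as.numeric(dm))
      } else {
        long <- tibble::tibble(
          !!sample := samp_ids[m@j + 1L],
          !!transcript := feat_ids[m@i + 1L],
          !!abundance := m@x)
      }
      tidy_expression_table(long, sample = sample, transcript = transcript,
                            abundance = abundance)
    }
  )
}

# delimited reader with exact (strtod) double parsing, so that write-read
# round trips reproduce doubles bit for bit; handles files, connections and
# gzip by extension
read_delim_exact <- function(path, delimiter = "\t") {
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  tibble::as_tibble(df)
}

#' Write an expression table to disk
#'
#' The long writer emits the key columns first (sample, transcript,
#' abundance), then the remaining columns in table order — a deterministic
#' canonical layout, so write-read-write round trips are byte identical.
#' Gzip compression is chosen by extension. Output is written to a
#' temporary file and atomically renamed, so no partial file is left on
#' error.
#'
#' @param x A `tidy_expression_table`.
#' @param path Output file (`"-"` for standard output in the CLI).
#' @param format `"long"` or `"wide"`.
#' @param delimiter Field delimiter (default tab).
#' @export
write_table <- function(x, path, format = c("long", "wide"),
                        delimiter = "\t") {
  stopifnot(is_tidy_expression_table(x))
  format <- match.arg(format)
  keys <- te_keys(x)
  out <- if (format == "long") {
    cols <- c(unlist(keys), setdiff(names(x), unlist(keys)))
    tibble::as_tibble(x)[, cols]
  } else {
    m <- te_assay(x)
    df <- tibble::as_tibble(m, rownames = keys$transcript)
    df
  }
  if (identical(path, "-")) {
    readr::write_delim(out, stdout(), delim = delimiter)
    return(invisible(path))
  }
  tmp <- tempfile(tmpdir = dirname(path),
                  fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  readr::write_delim(out, tmp, delim = delimiter)
  file.rename(tmp, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, member genes. Delegated to the
#' fgsea reader.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("data error: GMT file not found: ", path, call. = FALSE)
  }
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("usage error: the fgsea package is required to read GMT files",
         call. = FALSE)
  }
  fgsea::gmtPathways(path)
}

#' Read a signature matrix TSV
#'
#' Header required; first column transcript id, one column per cell type.
#'
#' @param path Signature TSV path.
#' @return Numeric matrix with transcript-id rownames.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) {
    stop("data error: signature file not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sig <- as.matrix(df[, -1, drop = FALSE])
  rownames(sig) <- as.character(df[[1]])
  sig
}
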