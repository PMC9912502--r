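#' Construct a validated count matrix
#'
#' Bundles a transcripts-by-samples matrix of raw counts with its sample
#' sheet. The sample sheet names, for every sample, the genetic cross it
#' belongs to, its role in the cross (`parent1`, `parent2` or `F1`) and a
#' replicate index. All downstream stages (normalization, differential
#' abundance, gene-action estimation) consume this container.
#'
#' @param counts integer matrix, transcripts in rows (rownames required),
#'   samples in columns (colnames required). All entries must be
#'   non-negative integers.
#' @param samples data frame with columns `sample_id`, `cross_id`, `role`
#'   (one of `"parent1"`, `"parent2"`, `"F1"`) and `replicate`. Every column
#'   of `counts` must appear exactly once.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `samples` (a tibble, ordered as the matrix columns).
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have transcript rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    abort(paste0("duplicate transcript_id in counts: ",
                 rownames(counts)[duplicated(rownames(counts))][1]))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    abort("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"

  samples <- as_tibble(samples)
  required <- c("sample_id", "cross_id", "role", "replicate")
  miss <- setdiff(required, names(samples))
  if (length(miss) > 0)
    abort(paste0("sample sheet is missing column(s): ",
                 paste(miss, collapse = ", ")))
  bad_role <- setdiff(unique(samples$role), c("parent1", "parent2", "F1"))
  if (length(bad_role) > 0)
    abort(paste0("unknown role value(s): ", paste(bad_role, collapse = ", "),
                 " (expected parent1, parent2, F1)"))
  if (anyDuplicated(samples$sample_id))
    abort("duplicate sample_id in sample sheet")
  if (!setequal(colnames(counts), samples$sample_id))
    abort(paste0(
      "sample sheet / count matrix mismatch; counts-only: ",
      paste(head(setdiff(colnames(counts), samples$sample_id), 3), collapse = ", "),
      "; sheet-only: ",
      paste(head(setdiff(samples$sample_id, colnames(counts)), 3), collapse = ", ")))
  samples <- samples[match(colnames(counts), samples$sample_id), ]

  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d transcripts x %d samples (%d cross(es))\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$cross_id))))
  print(dplyr::count(x$samples, .data$cross_id, .data$role))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read counts and a sample sheet from disk
#'
#' The counts file is either a TSV (first column `transcript_id`, remaining
#' columns one per sample, header row of sample ids) or a MatrixMarket
#' coordinate file; for MTX, row and column names are read from sibling
#' files `<path>.rownames` and `<path>.colnames` (one id per line), the
#' layout [write_counts()] produces. The sample sheet is TSV or CSV
#' (by extension) with columns `sample_id`, `cross_id`, `role`, `replicate`.
#'
#' @param counts_path path to the counts TSV or `.mtx` file.
#' @param samples_path path to the sample sheet.
#' @return a [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  if (grepl("\\.mtx$", counts_path)) {
    m <- as.matrix(Matrix::readMM(counts_path))
    rn <- readLines(paste0(counts_path, ".rownames"))
    cn <- readLines(paste0(counts_path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      abort("MTX dimensions do not match rownames/colnames files")
    dimnames(m) <- list(rn, cn)
  } else {
    tab <- readr::read_tsv(counts_path, show_col_types = FALSE,
                           progress = FALSE)
    if (names(tab)[1] != "transcript_id")
      abort("first column of the counts TSV must be named 'transcript_id'")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$transcript_id
  }
  reader <- if (grepl("\\.csv$", samples_path)) readr::read_csv else readr::read_tsv
  samples <- reader(samples_path, show_col_types = FALSE, progress = FALSE)
  count_matrix(m, samples)
}

#' Write a count matrix (and its sample sheet) to disk
#'
#' `format = "tsv"` writes a single TSV with a `transcript_id` first column.
#' `format = "mtx"` writes MatrixMarket coordinate format plus
#' `<path>.rownames` / `<path>.colnames` sidecar files. The sample sheet is
#' written as `<path without extension>_samples.tsv` unless `samples_path`
#' is given.
#'
#' @param m a [count_matrix()].
#' @param path output path for the counts.
#' @param format `"tsv"` or `"mtx"`.
#' @param samples_path optional explicit path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("tsv", "mtx"),
                         samples_path = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), path)
    writeLines(rownames(m$counts), paste0(path, ".rownames"))
    writeLines(colnames(m$counts), paste0(path, ".colnames"))
  } else {
    tab <- tibble(transcript_id = rownames(m$counts))
    tab <- dplyr::bind_cols(tab, as_tibble(m$counts))
    readr::write_tsv(tab, path, progress = FALSE)
  }
  if (is.null(samples_path))
    samples_path <- paste0(sub("\\.(tsv|mtx)$", "", path), "_samples.tsv")
  readr::write_tsv(m$samples, samples_path, progress = FALSE)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' Library-size normalization for count data: each sample's factor is the
#' median, over transcripts with all-positive counts, of the ratio of that
#' sample's count to the transcript's geometric mean across samples. This is
#' the standard median-of-ratios estimator used by negative binomial
#' differential expression frameworks; it is robust to a minority of
#' differentially abundant transcripts.
#'
#' @param m a [count_matrix()].
#' @return named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(m) {
  counts <- m$counts
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos))
    abort(paste0("no transcript has positive counts in every sample; ",
                 "size factors are undefined (consider adding a pseudocount ",
                 "or filtering samples)"))
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2,
              function(col) exp(median(log(col) - log_geo)))
  stats::setNames(sf, colnames(counts))
}

#' Counts normalized by size factors
#'
#' @param m a [count_matrix()].
#' @param sf optional precomputed size factors; defaults to
#'   [size_factors()] of `m`.
#' @return numeric matrix of normalized counts, same dimensions as the input.
#' @export
normalized_counts <- function(m, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(m)
  sweep(m$counts, 2, sf[colnames(m$counts)], "/")
}

#' Filter transcripts on median raw count
#'
#' Removes transcripts whose median raw count across the samples of a cross
#' is below `min_median` (the default 5 keeps a transcript whose counts are
#' all exactly 5). With several crosses in one matrix the median is taken
#' per cross and a transcript is retained if it passes in at least one.
#'
#' @param m a [count_matrix()].
#' @param min_median minimum per-cross median raw count (default 5).
#' @return a filtered [count_matrix()]; the number of removed transcripts is
#'   reported as a message and stored in `attr(, "n_removed")`.
#' @export
filter_low <- function(m, min_median = 5) {
  crosses <- unique(m$samples$cross_id)
  pass <- vapply(crosses, function(cr) {
    cols <- m$samples$sample_id[m$samples$cross_id == cr]
    apply(m$counts[, cols, drop = FALSE], 1, median) >= min_median
  }, logical(nrow(m$counts)))
  keep <- rowSums(as.matrix(pass)) > 0
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message(sprintf("filter_low: removed %d of %d transcripts (median < %g)",
                    n_removed, length(keep), min_median))
  out <- count_matrix(m$counts[keep, , drop = FALSE], m$samples)
  attr(out, "n_removed") <- n_removed
  out
}

#' @export
tidy.count_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "transcript_id") |>
    tidyr::pivot_longer(-"transcript_id", names_to = "sample_id",
                        values_to = "count") |>
    left_join(x$samples, by = "sample_id")
}

#' @export
glance.count_matrix <- function(x, ...) {
  tibble(n_transcripts = nrow(x$counts), n_samples = ncol(x$counts),
         n_crosses = length(unique(x$samples$cross_id)),
         total_counts = sum(as.numeric(x$counts)))
}
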