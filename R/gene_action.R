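#' Additive effect
#'
#' Half the difference between the two parental means,
#' `a = (X1 - X2) / 2`: the expected phenotypic effect of substituting one
#' parental allele for the other.
#'
#' @param x1,x2 mean normalized abundance of parent 1 and parent 2
#'   (vectorized).
#' @return numeric vector of additive effects, same units as the inputs.
#' @export
additive_effect <- function(x1, x2) {
  if (any(!is.finite(x1)) || any(!is.finite(x2)))
    abort("additive_effect: inputs must be finite")
  (x1 - x2) / 2
}

#' Dominance effect
#'
#' Deviation of the F1 hybrid mean from the mid-parent value,
#' `d = F1 - (X1 + X2) / 2`.
#'
#' @param f1 mean normalized abundance of the F1 hybrid (vectorized).
#' @inheritParams additive_effect
#' @return numeric vector of dominance effects.
#' @export
dominance_effect <- function(f1, x1, x2) {
  if (any(!is.finite(f1)) || any(!is.finite(x1)) || any(!is.finite(x2)))
    abort("dominance_effect: inputs must be finite")
  f1 - (x1 + x2) / 2
}

#' Degree of dominance
#'
#' The ratio `k = d / a` of the dominance to the additive effect: 0 for
#' purely additive gene action, |1| for complete dominance of one allele,
#' beyond |1.25| for transgressive action (F1 outside the parental range).
#' Where the additive effect is negligible (`|a| <= a_tol`) the ratio is
#' undefined and `NA` is returned rather than a huge or infinite value.
#'
#' @param d dominance effect(s).
#' @param a additive effect(s).
#' @param a_tol absolute tolerance below which `a` counts as zero
#'   (default 1e-8).
#' @return numeric vector of signed k values, `NA` where undefined.
#' @export
degree_of_dominance <- function(d, a, a_tol = 1e-8) {
  ifelse(abs(a) > a_tol, d / a, NA_real_)
}

#' Classify the degree of dominance into gene-action categories
#'
#' Maps `|k|` to one of four categories using half-open intervals, so each
#' boundary value belongs to the upper (more dominant) category:
#' `additive` for `|k| < b1`, `partial_dominant` for `b1 <= |k| < b2`,
#' `dominant_recessive` for `b2 <= |k| < b3`, `transgressive` for
#' `|k| >= b3`, with default boundaries `(0.25, 0.75, 1.25)`. `NA` k maps
#' to `undefined`.
#'
#' @param k signed degree(s) of dominance.
#' @param boundaries increasing numeric vector of three category bounds.
#' @return factor with levels additive, partial_dominant,
#'   dominant_recessive, transgressive, undefined.
#' @export
classify_gene_action <- function(k, boundaries = c(0.25, 0.75, 1.25)) {
  if (length(boundaries) != 3 || any(diff(boundaries) <= 0))
    abort("`boundaries` must be three strictly increasing values")
  ak <- abs(k)
  out <- dplyr::case_when(
    is.na(ak) ~ "undefined",
    ak < boundaries[1] ~ "additive",
    ak < boundaries[2] ~ "partial_dominant",
    ak < boundaries[3] ~ "dominant_recessive",
    TRUE ~ "transgressive")
  factor(out, levels = GA_CATEGORIES)
}

#' Per-transcript gene-action table
#'
#' Computes, for every (differentially expressed) transcript of every cross,
#' the additive effect `a`, dominance effect `d`, degree of dominance
#' `k = d / a` and the discrete gene-action category, from the mean
#' normalized abundances of the two parents and the F1 hybrid. k is left
#' unclipped; restrict to the conventional plotting range afterwards if
#' needed. Rows where k is undefined (negligible `a`, or a missing role
#' mean) are retained with category `undefined` and counted in a message.
#'
#' @param de DE tibble from [de_test()] or [read_de_table()] (needs columns
#'   `cross_id`, `transcript_id`, `X1_bar`, `X2_bar`, `F1_bar`, `is_DE`).
#' @param only_de keep only transcripts flagged `is_DE` (default TRUE, the
#'   convention for inheritance analyses: k is interpreted where the
#'   parents actually differ).
#' @param a_tol relative tolerance for treating `a` as zero; the absolute
#'   tolerance used per row is `a_tol * max(X1, X2, 1)`.
#' @param boundaries category boundaries, see [classify_gene_action()].
#' @return a `gene_action_tbl` tibble with columns `cross_id`,
#'   `transcript_id`, `X1`, `X2`, `F1`, `a`, `d`, `k`, `category`.
#' @export
gene_action_table <- function(de, only_de = TRUE, a_tol = 1e-8,
                              boundaries = c(0.25, 0.75, 1.25)) {
  if (only_de) de <- filter(de, .data$is_DE)
  out <- de |>
    select("cross_id", "transcript_id",
           X1 = "X1_bar", X2 = "X2_bar", F1 = "F1_bar") |>
    mutate(
      a = (.data$X1 - .data$X2) / 2,
      d = .data$F1 - (.data$X1 + .data$X2) / 2,
      k = degree_of_dominance(.data$d, .data$a,
                              a_tol = a_tol * pmax(.data$X1, .data$X2, 1)),
      k = ifelse(is.na(.data$F1), NA_real_, .data$k),
      category = classify_gene_action(.data$k, boundaries))
  n_undef <- sum(out$category == "undefined")
  if (n_undef > 0)
    message(sprintf("gene_action_table: %d of %d transcripts have undefined k",
                    n_undef, nrow(out)))
  class(out) <- c("gene_action_tbl", class(out))
  out
}

#' @export
glance.gene_action_tbl <- function(x, ...) {
  x |>
    group_by(.data$cross_id) |>
    summarise(n = dplyr::n(),
              n_undefined = sum(.data$category == "undefined"),
              additive = mean(.data$category == "additive"),
              partial_dominant = mean(.data$category == "partial_dominant"),
              dominant_recessive = mean(.data$category == "dominant_recessive"),
              transgressive = mean(.data$category == "transgressive"),
              median_abs_k = median(abs(.data$k), na.rm = TRUE),
              .groups = "drop")
}

#' Write a gene-action table as TSV
#' @param ga tibble from [gene_action_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_action <- function(ga, path) {
  readr::write_tsv(ga, path, progress = FALSE)
  invisible(path)
}
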