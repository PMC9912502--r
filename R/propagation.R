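#' Gene-action similarity of a regulator-target pair
#'
#' The similarity index `s = |log2(|k_REG| / |k_TAR|)|`: 0 when regulator
#' and target have the same absolute degree of dominance, growing as the
#' two diverge. Absolute values are taken inside the ratio because signed k
#' ratios can be negative; pairs where either `|k|` does not exceed
#' `k_floor` are returned as `NA` (the ratio would be unbounded).
#'
#' @param k_reg,k_tar signed degrees of dominance (vectorized).
#' @param k_floor magnitude floor below which a k is treated as zero
#'   (default 1e-3).
#' @return numeric vector of similarities, `NA` where excluded.
#' @export
edge_similarity <- function(k_reg, k_tar, k_floor = 1e-3) {
  ok <- !is.na(k_reg) & !is.na(k_tar) &
    abs(k_reg) > k_floor & abs(k_tar) > k_floor
  ifelse(ok, abs(log2(abs(k_reg) / abs(k_tar))), NA_real_)
}

#' Per-edge similarity table for a network
#'
#' Joins a gene-action table onto the edges of a (sub-)network and computes
#' the similarity index for every non-self edge whose two endpoints both
#' have defined k above the magnitude floor. Self-edges (trivially similar)
#' and excluded edges are counted in attributes; sign-discordant edges
#' (k_REG and k_TAR of opposite sign) are flagged so analyses can be rerun
#' without them.
#'
#' @param grn edge-list tibble.
#' @param ga gene-action tibble from [gene_action_table()] (columns
#'   `transcript_id`, `k`, `category`).
#' @param k_floor see [edge_similarity()].
#' @return tibble: `regulator`, `target`, `k_reg`, `k_tar`, `s`,
#'   `sign_discordant`, `reg_category`, `tar_category`; attributes
#'   `n_self_edges`, `n_excluded` report the dropped edges.
#' @export
edge_similarity_table <- function(grn, ga, k_floor = 1e-3) {
  kmap <- select(ga, gene_id = "transcript_id", "k", "category")
  n_self <- sum(grn$regulator == grn$target)
  est <- grn |>
    filter(.data$regulator != .data$target) |>
    left_join(rename(kmap, k_reg = "k", reg_category = "category"),
              by = c(regulator = "gene_id")) |>
    left_join(rename(kmap, k_tar = "k", tar_category = "category"),
              by = c(target = "gene_id")) |>
    mutate(s = edge_similarity(.data$k_reg, .data$k_tar, k_floor),
           sign_discordant = sign(.data$k_reg) != sign(.data$k_tar))
  n_excl <- sum(is.na(est$s))
  est <- filter(est, !is.na(.data$s)) |>
    select("regulator", "target", "k_reg", "k_tar", "s", "sign_discordant",
           "reg_category", "tar_category")
  attr(est, "n_self_edges") <- n_self
  attr(est, "n_excluded") <- n_excl
  est
}

#' Median similarity by regulator gene-action category
#'
#' Groups the per-edge similarities by the regulator's gene-action category
#' and summarises each group; smaller median s means the regulator's mode
#' of gene action is propagated more faithfully to its targets.
#'
#' @param est tibble from [edge_similarity_table()].
#' @return tibble: `reg_category`, `n_edges`, `n_regulators`, `median_s`,
#'   `mean_s`.
#' @export
similarity_by_regulator_category <- function(est) {
  if (nrow(est) == 0) abort("empty similarity table")
  est |>
    group_by(reg_category = factor(.data$reg_category,
                                   levels = GA_CATEGORIES)) |>
    summarise(n_edges = dplyr::n(),
              n_regulators = dplyr::n_distinct(.data$regulator),
              median_s = median(.data$s), mean_s = mean(.data$s),
              .groups = "drop")
}

#' Pairwise Wilcoxon rank-sum tests between labelled groups
#'
#' Two-sided rank-sum test for every unordered pair of groups: exact when
#' the combined sample size is at most 20 and there are no ties, the
#' normal approximation with tie correction otherwise. The effect size
#' `r = |Z| / sqrt(n1 + n2)` is back-computed from the two-sided p-value.
#' Pairs involving a group of fewer than 2 values are skipped with a
#' warning.
#'
#' @param values numeric vector (e.g. similarities s).
#' @param groups group labels, same length.
#' @return tibble: `group1`, `group2`, `W`, `pvalue`, `effect_r`, `n1`,
#'   `n2`.
#' @export
pairwise_wilcoxon <- function(values, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2) abort("pairwise_wilcoxon: need at least 2 groups")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    g1 <- values[groups == pr[1]]; g2 <- values[groups == pr[2]]
    if (length(g1) < 2 || length(g2) < 2) {
      warn(sprintf("skipping pair %s vs %s (group with n < 2)",
                   pr[1], pr[2]))
      return(NULL)
    }
    n <- length(g1) + length(g2)
    ht <- suppressWarnings(
      wilcox.test(g1, g2, exact = n <= 20, correct = TRUE))
    p <- min(ht$p.value, 1)
    tibble(group1 = pr[1], group2 = pr[2], W = unname(ht$statistic),
           pvalue = p, effect_r = abs(qnorm(p / 2)) / sqrt(n),
           n1 = length(g1), n2 = length(g2))
  }) |> bind_rows()
}

#' Binomial test on a regulator's target gene-action spectrum
#'
#' Exact binomial tail probability of observing at most (one-sided
#' `"less"`, the default) the given number of, say, additive targets among
#' `n_targets`, under a null probability `p0` (for instance the global
#' additive fraction among sub-network targets). `p0` is echoed in the
#' output because conclusions depend on it.
#'
#' @param n_observed number of targets in the focal category.
#' @param n_targets total targets with a defined category.
#' @param p0 null probability in (0, 1).
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @return one-row tibble: `n_observed`, `n_targets`, `p0`, `alternative`,
#'   `pvalue`.
#' @export
regulator_target_binomial <- function(n_observed, n_targets, p0,
                                      alternative = c("less", "greater",
                                                      "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    abort("`p0` must lie strictly between 0 and 1")
  if (n_targets < 1 || n_observed < 0 || n_observed > n_targets)
    abort("need 0 <= n_observed <= n_targets and n_targets >= 1")
  ht <- binom.test(n_observed, n_targets, p = p0, alternative = alternative)
  tibble(n_observed = n_observed, n_targets = n_targets, p0 = p0,
         alternative = alternative, pvalue = ht$p.value)
}

#' Export a gene-action-annotated network
#'
#' Writes GraphML (and a TSV twin) for a sub-network: node attribute
#' `category` is the gene-action category (`"undefined"` for nodes without
#' k), edge attribute `s` the similarity index (`NA` for edges excluded by
#' the magnitude floor).
#'
#' @param grn edge-list tibble.
#' @param est similarity tibble from [edge_similarity_table()].
#' @param ga gene-action tibble.
#' @param path output `.graphml` path (a `.tsv` twin is written alongside).
#' @return `path`, invisibly.
#' @export
export_annotated_network <- function(grn, est, ga, path) {
  edges <- grn |>
    left_join(select(est, "regulator", "target", "s"),
              by = c("regulator", "target"))
  nodes <- tibble(gene_id = unique(c(grn$regulator, grn$target))) |>
    left_join(select(ga, gene_id = "transcript_id", "category"),
              by = "gene_id") |>
    mutate(category = as.character(
      ifelse(is.na(.data$category), "undefined", as.character(.data$category))))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  readr::write_tsv(edges, sub("\\.graphml$", ".tsv", path), progress = FALSE)
  invisible(path)
}
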