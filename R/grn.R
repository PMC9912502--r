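#' Read a directed gene regulatory network edge list
#'
#' TSV with header columns `regulator` and `target` (an optional `weight`
#' column, e.g. mutual information, is carried along). Duplicate
#' (regulator, target) pairs are collapsed with a warning; self-edges are
#' permitted and counted.
#'
#' @param path TSV path.
#' @return tibble with columns `regulator`, `target` (and `weight` if
#'   present); attribute `n_self_edges` holds the self-edge count.
#' @export
read_grn <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  grn_edges(tab)
}

#' Validate an in-memory edge list
#' @param edges data frame with `regulator` and `target` columns.
#' @return deduplicated tibble with the self-edge count attribute.
#' @export
grn_edges <- function(edges) {
  if (!all(c("regulator", "target") %in% names(edges)))
    abort("edge list needs columns 'regulator' and 'target'")
  edges <- as_tibble(edges)
  n0 <- nrow(edges)
  edges <- distinct(edges, .data$regulator, .data$target, .keep_all = TRUE)
  if (nrow(edges) < n0)
    warn(sprintf("collapsed %d duplicate edge(s)", n0 - nrow(edges)))
  attr(edges, "n_self_edges") <- sum(edges$regulator == edges$target)
  edges
}

#' In- and out-degrees of every network node
#'
#' Out-degree is the number of distinct targets a node regulates; in-degree
#' the number of distinct regulators controlling it. A node is flagged as a
#' regulator when its out-degree is at least one. Self-edges count toward
#' both degrees.
#'
#' @param grn edge-list tibble from [read_grn()] / [grn_edges()].
#' @return tibble: `gene_id`, `out_degree`, `in_degree`, `is_regulator`.
#' @export
grn_degrees <- function(grn) {
  nodes <- unique(c(grn$regulator, grn$target))
  outd <- table(factor(grn$regulator, levels = nodes))
  ind <- table(factor(grn$target, levels = nodes))
  tibble(gene_id = nodes,
         out_degree = as.integer(outd[nodes]),
         in_degree = as.integer(ind[nodes]),
         is_regulator = as.integer(outd[nodes]) >= 1)
}

#' Induced sub-network on a gene set
#'
#' Keeps edges with both endpoints in `genes` (e.g. the differentially
#' expressed transcripts of a cross). Nodes with at least one out-edge in
#' the sub-graph are counted as regulators, the remaining nodes as targets;
#' self-edges are counted separately.
#'
#' @param grn edge-list tibble.
#' @param genes character vector of gene ids.
#' @return the induced edge-list tibble, with attribute `partition`, a
#'   one-row tibble (`n_regulators`, `n_targets`, `n_self_edges`,
#'   `n_edges`).
#' @export
extract_subnetwork <- function(grn, genes) {
  sub <- filter(grn, .data$regulator %in% genes, .data$target %in% genes)
  if (nrow(sub) == 0)
    warn("extract_subnetwork: no edge has both endpoints in the gene set")
  regs <- unique(sub$regulator)
  tars <- setdiff(unique(sub$target), regs)
  attr(sub, "partition") <- tibble(
    n_regulators = length(regs), n_targets = length(tars),
    n_self_edges = sum(sub$regulator == sub$target), n_edges = nrow(sub))
  attr(sub, "n_self_edges") <- sum(sub$regulator == sub$target)
  sub
}

#' Correlate network connectivity with divergence and dominance
#'
#' Joins node degrees with per-transcript expression divergence
#' (`|log2FC|`) and absolute degree of dominance (`|k|`), then reports four
#' associations: divergence vs out-degree (regulators only), divergence vs
#' in-degree (targets, i.e. in-degree >= 1), `|k|` vs out-degree and `|k|`
#' vs in-degree. Both Spearman and Pearson coefficients are always
#' computed; `method` selects which one leads the output ordering.
#'
#' @param deg degree tibble from [grn_degrees()].
#' @param de DE tibble from [de_test()] (for `log2FC`).
#' @param ga gene-action tibble from [gene_action_table()] (for `k`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return tibble: `response`, `predictor`, `method`, `estimate`, `pvalue`,
#'   `n`; zero-variance pairs are flagged with `NA` estimate.
#' @export
connectivity_correlations <- function(deg, de, ga,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  joined <- deg |>
    left_join(select(de, gene_id = "transcript_id", "log2FC"),
              by = "gene_id") |>
    left_join(select(ga, gene_id = "transcript_id", "k"), by = "gene_id") |>
    mutate(abs_lfc = abs(.data$log2FC), abs_k = abs(.data$k))

  specs <- list(
    list("abs_lfc", "out_degree", quote(.data$is_regulator)),
    list("abs_lfc", "in_degree", quote(.data$in_degree >= 1)),
    list("abs_k", "out_degree", quote(.data$is_regulator)),
    list("abs_k", "in_degree", quote(.data$in_degree >= 1)))
  out <- purrr::map(specs, function(sp) {
    sub <- filter(joined, !!sp[[3]])
    x <- sub[[sp[[2]]]]; y <- sub[[sp[[1]]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3)
      abort(sprintf("connectivity_correlations: fewer than 3 usable rows for %s vs %s",
                    sp[[1]], sp[[2]]))
    purrr::map(c("spearman", "pearson"), function(mm) {
      if (var(x) == 0 || var(y) == 0)
        return(tibble(response = sp[[1]], predictor = sp[[2]], method = mm,
                      estimate = NA_real_, pvalue = NA_real_,
                      n = length(x)))
      ht <- suppressWarnings(cor.test(x, y, method = mm, exact = FALSE))
      tibble(response = sp[[1]], predictor = sp[[2]], method = mm,
             estimate = unname(ht$estimate), pvalue = ht$p.value,
             n = length(x))
    }) |> bind_rows()
  }) |> bind_rows()
  arrange(out, .data$method != method)
}

#' Loess curve on an equally spaced grid
#'
#' Tricube-weighted local linear regression (`stats::loess`, `degree = 1`,
#' exact `"direct"` surface) evaluated on a grid over the predictor range;
#' the companion to the connectivity scatter plots.
#'
#' @param x,y numeric vectors (at least 10 points).
#' @param span loess span (default 0.75).
#' @param n_grid grid size (default 100).
#' @return tibble with columns `x`, `fitted`.
#' @export
loess_curve <- function(x, y, span = 0.75, n_grid = 100) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10)
    abort("loess_curve: need at least 10 finite points")
  fit <- loess(y ~ x, data = tibble(x = x, y = y), span = span, degree = 1,
               surface = "direct")
  grid <- seq(min(x), max(x), length.out = n_grid)
  tibble(x = grid, fitted = as.numeric(predict(fit, newdata = tibble(x = grid))))
}

#' Write an edge list (with optional node attributes) to GraphML
#' @param grn edge-list tibble.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_grn_graphml <- function(grn, path) {
  g <- igraph::graph_from_data_frame(grn, directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
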