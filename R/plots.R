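#' Density of the degree of dominance per regime
#'
#' @param pooled tibble from [pool_k()].
#' @param clip display clip for |k| (default 5, the conventional plotting
#'   range); set `Inf` to disable.
#' @return a ggplot object.
#' @export
plot_k_density <- function(pooled, clip = 5) {
  dat <- filter(pooled, abs(.data$k) <= clip)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k, colour = .data$regime)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "degree of dominance (k)", y = "density",
                  colour = "regime") +
    ggplot2::theme_minimal()
}

#' Empirical CDF of the degree of dominance per regime
#' @inheritParams plot_k_density
#' @return a ggplot object.
#' @export
plot_k_ecdf <- function(pooled, clip = 5) {
  dat <- filter(pooled, abs(.data$k) <= clip)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k, colour = .data$regime)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "degree of dominance (k)", y = "ECDF",
                  colour = "regime") +
    ggplot2::theme_minimal()
}

#' Gene-action category proportions per regime
#' @inheritParams plot_k_density
#' @return a ggplot object.
#' @export
plot_category_proportions <- function(pooled) {
  props <- regime_summary(pooled)$proportions
  ggplot2::ggplot(props, ggplot2::aes(x = .data$regime,
                                      y = .data$proportion,
                                      fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of transcripts",
                  fill = "gene action") +
    ggplot2::theme_minimal()
}

#' Regulator-target similarity by regulator gene-action category
#'
#' Violin + boxplot of the per-edge similarity index s grouped by the
#' regulator's category; lower s means the regulator's gene action is
#' reproduced more faithfully in its targets.
#'
#' @param est tibble from [edge_similarity_table()].
#' @return a ggplot object.
#' @export
plot_similarity_by_category <- function(est) {
  ggplot2::ggplot(est, ggplot2::aes(x = .data$reg_category, y = .data$s)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::labs(x = "regulator gene action",
                  y = expression("|log"[2] * "(|k"["REG"] *
                                   "| / |k"["TAR"] * "|)|")) +
    ggplot2::theme_minimal()
}

#' Connectivity vs divergence/dominance scatter with loess curve
#'
#' @param deg degree tibble from [grn_degrees()].
#' @param values named numeric vector (gene_id -> value, e.g. `|log2FC|`
#'   or `|k|`).
#' @param degree `"out_degree"` or `"in_degree"`.
#' @param span loess span.
#' @return a ggplot object.
#' @export
plot_connectivity <- function(deg, values, degree = c("out_degree",
                                                      "in_degree"),
                              span = 0.75) {
  degree <- match.arg(degree)
  dat <- deg |>
    mutate(value = unname(values[.data$gene_id])) |>
    filter(is.finite(.data$value))
  curve <- loess_curve(dat[[degree]], dat$value, span = span)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[degree]], y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$x, y = .data$fitted),
                       colour = "firebrick") +
    ggplot2::labs(x = gsub("_", "-", degree), y = "value") +
    ggplot2::theme_minimal()
}
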