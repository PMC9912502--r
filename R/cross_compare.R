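#' Pool per-cross k values into selection-regime samples
#'
#' Crosses are grouped into selection regimes (e.g. `natural_selection`,
#' `domestication`, `inbreds`) and their finite k values concatenated per
#' regime, retaining provenance. Undefined-k rows are dropped from the pool
#' and counted in a message; an empty regime yields a warning.
#'
#' @param ga a gene-action tibble from [gene_action_table()] (or several
#'   row-bound together).
#' @param regimes named character vector or two-column data frame
#'   (`cross_id`, `regime`) assigning every cross to exactly one regime.
#' @return tibble with columns `regime`, `cross_id`, `transcript_id`, `k`,
#'   `category`.
#' @export
pool_k <- function(ga, regimes) {
  if (is.data.frame(regimes)) {
    if (!all(c("cross_id", "regime") %in% names(regimes)))
      abort("`regimes` data frame needs columns cross_id and regime")
    map <- stats::setNames(regimes$regime, regimes$cross_id)
  } else map <- regimes
  unassigned <- setdiff(unique(ga$cross_id), names(map))
  if (length(unassigned) > 0)
    abort(paste0("cross(es) without regime assignment: ",
                 paste(unassigned, collapse = ", ")))
  n_undef <- sum(is.na(ga$k))
  if (n_undef > 0)
    message(sprintf("pool_k: dropped %d undefined-k rows", n_undef))
  empty <- setdiff(unique(unname(map)), unname(map[unique(ga$cross_id)]))
  if (length(empty) > 0)
    warn(paste0("regime(s) with no crosses in the data: ",
                paste(empty, collapse = ", ")))
  ga |>
    filter(!is.na(.data$k)) |>
    mutate(regime = unname(map[.data$cross_id])) |>
    select("regime", "cross_id", "transcript_id", "k", "category") |>
    as_tibble()
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The D statistic is the exact supremum distance between the two empirical
#' cumulative distribution functions; the p-value is the asymptotic
#' two-sided Kolmogorov approximation by default (`exact = NULL` lets
#' [stats::ks.test()] pick the exact distribution for small samples).
#'
#' @param s1,s2 numeric samples (k values of two regimes).
#' @param exact passed to [stats::ks.test()]; default `FALSE` (asymptotic).
#' @param absolute compare `|k|` instead of signed k.
#' @return one-row tibble: `D`, `pvalue`, `n1`, `n2`, `absolute`.
#' @export
ks_two_sample <- function(s1, s2, exact = FALSE, absolute = FALSE) {
  s1 <- s1[is.finite(s1)]; s2 <- s2[is.finite(s2)]
  if (length(s1) < 1 || length(s2) < 1)
    abort("ks_two_sample: both samples must be non-empty")
  if (absolute) { s1 <- abs(s1); s2 <- abs(s2) }
  ht <- suppressWarnings(ks.test(s1, s2, exact = exact))
  tibble(D = unname(ht$statistic), pvalue = ht$p.value,
         n1 = length(s1), n2 = length(s2), absolute = absolute)
}

#' Fisher's exact test on additive fractions
#'
#' Compares the proportion of additive transcripts between two regimes with
#' a two-sided Fisher's exact test on the 2x2 table
#' (additive, non-additive) x (regime 1, regime 2). The two-sided p-value
#' sums hypergeometric point probabilities no larger than the observed
#' table's; the odds ratio is the conditional MLE.
#'
#' @param add1,tot1 additive count and total for regime 1.
#' @param add2,tot2 additive count and total for regime 2.
#' @return one-row tibble: `odds_ratio`, `pvalue`, `frac1`, `frac2`.
#' @export
additive_fraction_test <- function(add1, tot1, add2, tot2) {
  tab <- matrix(c(add1, tot1 - add1, add2, tot2 - add2), nrow = 2,
                byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab)))
    abort("additive_fraction_test: counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate margin in 2x2 table; p = 1")
    return(tibble(odds_ratio = NA_real_, pvalue = 1,
                  frac1 = add1 / max(tot1, 1), frac2 = add2 / max(tot2, 1)))
  }
  ht <- fisher.test(tab)
  tibble(odds_ratio = unname(ht$estimate), pvalue = ht$p.value,
         frac1 = add1 / tot1, frac2 = add2 / tot2)
}

#' Compare pooled k distributions across all regime pairs
#'
#' Runs [ks_two_sample()] on signed k (and optionally `|k|`) and
#' [additive_fraction_test()] for every unordered pair of regimes in a
#' pooled table.
#'
#' @param pooled tibble from [pool_k()].
#' @param absolute also report KS on `|k|`.
#' @return list of tibbles: `ks` (one row per pair x scale) and
#'   `additive_fraction` (one row per pair).
#' @export
compare_regimes <- function(pooled, absolute = TRUE) {
  regs <- unique(pooled$regime)
  pairs <- utils::combn(regs, 2, simplify = FALSE)
  ks <- purrr::map(pairs, function(pr) {
    s1 <- pooled$k[pooled$regime == pr[1]]
    s2 <- pooled$k[pooled$regime == pr[2]]
    out <- ks_two_sample(s1, s2)
    if (absolute) out <- bind_rows(out, ks_two_sample(s1, s2, absolute = TRUE))
    mutate(out, regime1 = pr[1], regime2 = pr[2], .before = 1)
  }) |> bind_rows()
  af <- purrr::map(pairs, function(pr) {
    g1 <- pooled[pooled$regime == pr[1], ]
    g2 <- pooled[pooled$regime == pr[2], ]
    additive_fraction_test(sum(g1$category == "additive"), nrow(g1),
                           sum(g2$category == "additive"), nrow(g2)) |>
      mutate(regime1 = pr[1], regime2 = pr[2], .before = 1)
  }) |> bind_rows()
  list(ks = ks, additive_fraction = af)
}

#' Per-regime ECDF, density and category proportions
#'
#' Summarises each regime's pooled k sample: the empirical CDF evaluated on
#' the pooled sorted support of all regimes, a Gaussian-kernel density on a
#' common equally spaced grid (Silverman's rule-of-thumb bandwidth), and
#' the proportion of transcripts in each gene-action category.
#'
#' @param pooled tibble from [pool_k()].
#' @param n_grid number of density grid points (default 256).
#' @return list of tibbles `ecdf` (`regime`, `x`, `F`), `density`
#'   (`regime`, `x`, `y`) and `proportions` (`regime`, `category`, `n`,
#'   `proportion`).
#' @export
regime_summary <- function(pooled, n_grid = 256) {
  if (nrow(pooled) == 0) abort("regime_summary: empty pool")
  support <- sort(unique(pooled$k))
  grid <- seq(min(pooled$k), max(pooled$k), length.out = n_grid)
  by_reg <- split(pooled$k, pooled$regime)
  ecdf_tab <- purrr::imap(by_reg, function(ks, reg) {
    tibble(regime = reg, x = support, F = ecdf(ks)(support))
  }) |> bind_rows()
  dens_tab <- purrr::imap(by_reg, function(ks, reg) {
    d <- density(ks, bw = "nrd0", from = min(grid), to = max(grid),
                 n = n_grid)
    tibble(regime = reg, x = d$x, y = d$y)
  }) |> bind_rows()
  props <- pooled |>
    count(.data$regime, .data$category, .drop = FALSE) |>
    filter(.data$category != "undefined") |>
    group_by(.data$regime) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup()
  list(ecdf = ecdf_tab, density = dens_tab, proportions = props)
}
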