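#' Negative binomial Wald test for parent-vs-parent differential abundance
#'
#' Tests, per transcript and per cross, whether normalized abundance differs
#' between the two F0 parents. Counts are normalized with median-of-ratios
#' size factors computed across all samples of the cross (parents and F1),
#' so the F1 mean reported alongside is on the same scale. The test is a
#' Wald test on the difference of log2 group means: the per-transcript NB
#' dispersion is estimated by method of moments from the within-parent
#' residual variance of normalized counts, floored at `disp_floor`; the
#' variance of each group mean is `(mu + disp * mu^2) / n` and is mapped to
#' the log2 scale by the delta method. The statistic is referred to a t
#' distribution with `n1 + n2 - 1` degrees of freedom: the SE mixes a known
#' Poisson component with an overdispersion component estimated on
#' `n1 + n2 - 2` residual df, so the effective df lies above the residual
#' df; this choice gives calibrated null p-values in simulation.
#' P-values are Benjamini-Hochberg adjusted across tested transcripts of
#' the cross.
#'
#' Transcripts with zero counts in both parents are excluded from testing
#' (flagged `"zero_both_parents"`, `pvalue = NA`) so the BH family size
#' equals the number of tests actually performed. Transcripts with zero
#' mean in exactly one parent have a degenerate Wald statistic; inside the
#' statistic only, the zero group mean is floored at `0.5 / n_reps` (the
#' reported means and `log2FC` are untouched, so `log2FC` is infinite
#' there), and the row is flagged `"zero_one_parent"`.
#'
#' @param m a [count_matrix()], typically already passed through
#'   [filter_low()].
#' @param alpha FDR threshold for the `is_DE` call (default 0.05).
#' @param lfc_min minimum `|log2FC|` for the `is_DE` call (default 0.5).
#' @param disp_floor lower bound for the method-of-moments dispersion
#'   (default 1e-8, effectively Poisson).
#' @return a tibble (one row per transcript per cross) with columns
#'   `cross_id`, `transcript_id`, `X1_bar`, `X2_bar`, `F1_bar` (mean
#'   normalized abundance per role), `log2FC` (`log2(X1_bar / X2_bar)`),
#'   `dispersion`, `stat`, `pvalue`, `padj`, `is_DE`, `status`.
#' @export
de_test <- function(m, alpha = 0.05, lfc_min = 0.5, disp_floor = 1e-8) {
  purrr::map(unique(m$samples$cross_id), function(cr) {
    sub <- count_matrix(
      m$counts[, m$samples$sample_id[m$samples$cross_id == cr], drop = FALSE],
      m$samples[m$samples$cross_id == cr, ])
    de_test_one(sub, cr, alpha, lfc_min, disp_floor)
  }) |> bind_rows()
}

de_test_one <- function(m, cross_id, alpha, lfc_min, disp_floor) {
  roles <- m$samples$role
  n1 <- sum(roles == "parent1"); n2 <- sum(roles == "parent2")
  if (n1 < 2 || n2 < 2)
    abort(sprintf("cross '%s': need >= 2 replicates per parent (got %d, %d)",
                  cross_id, n1, n2))
  norm <- normalized_counts(m)
  x1 <- norm[, roles == "parent1", drop = FALSE]
  x2 <- norm[, roles == "parent2", drop = FALSE]
  f1 <- norm[, roles == "F1", drop = FALSE]

  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  mf <- if (ncol(f1) > 0) rowMeans(f1) else rep(NA_real_, nrow(norm))

  # pooled within-parent residual variance -> MoM dispersion
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  var_w <- ss / (n1 + n2 - 2)
  mu_pool <- (n1 * m1 + n2 * m2) / (n1 + n2)
  disp <- pmax((var_w - mu_pool) / mu_pool^2, disp_floor)

  status <- rep("tested", nrow(norm))
  status[m1 == 0 & m2 == 0] <- "zero_both_parents"
  status[xor(m1 == 0, m2 == 0)] <- "zero_one_parent"

  # mean floor used only inside the Wald statistic (degenerate at mu = 0)
  floor1 <- pmax(m1, 0.5 / n1)
  floor2 <- pmax(m2, 0.5 / n2)
  v1 <- (floor1 + disp * floor1^2) / n1
  v2 <- (floor2 + disp * floor2^2) / n2
  se_log2 <- sqrt(v1 / (floor1^2) + v2 / (floor2^2)) / log(2)
  stat <- (log2(floor1) - log2(floor2)) / se_log2
  pvalue <- 2 * pt(-abs(stat), df = n1 + n2 - 1)
  pvalue[status == "zero_both_parents"] <- NA_real_
  stat[status == "zero_both_parents"] <- NA_real_

  tested <- !is.na(pvalue)
  padj <- rep(NA_real_, length(pvalue))
  padj[tested] <- p.adjust(pvalue[tested], method = "BH")

  log2fc <- log2(m1 / m2)
  m1 <- unname(m1); m2 <- unname(m2); mf <- unname(mf)
  log2fc <- unname(log2fc); disp <- unname(disp); stat <- unname(stat)
  pvalue <- unname(pvalue); padj <- unname(padj)
  tibble(cross_id = cross_id, transcript_id = rownames(norm),
         X1_bar = m1, X2_bar = m2, F1_bar = mf,
         log2FC = log2fc, dispersion = disp, stat = stat,
         pvalue = pvalue, padj = padj,
         is_DE = !is.na(padj) & padj <= alpha & abs(log2fc) > lfc_min,
         status = status)
}

#' Import a precomputed differential expression table
#'
#' Lets any external DE caller stand in for [de_test()]: the TSV must carry
#' the same columns (`cross_id`, `transcript_id`, `X1_bar`, `X2_bar`,
#' `F1_bar`, `log2FC`, `pvalue`, `padj`); `is_DE` is recomputed from the
#' thresholds so the downstream contract is identical.
#'
#' @param path TSV path.
#' @inheritParams de_test
#' @return a DE tibble as from [de_test()] (without `dispersion`/`stat`
#'   unless present in the file).
#' @export
read_de_table <- function(path, alpha = 0.05, lfc_min = 0.5) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cross_id", "transcript_id", "X1_bar", "X2_bar", "F1_bar",
                "log2FC", "pvalue", "padj")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0)
    abort(paste0("DE table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  tab |>
    mutate(is_DE = !is.na(.data$padj) & .data$padj <= alpha &
             abs(.data$log2FC) > lfc_min)
}

#' Write a DE table as TSV
#' @param de tibble from [de_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(de, path, progress = FALSE)
  invisible(path)
}
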