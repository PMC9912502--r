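test_that("edge lists read, deduplicate and count self-edges", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    regulator = c("A", "A", "B"), target = c("B", "C", "C")), tmp)
  g <- read_grn(tmp)
  expect_equal(nrow(g), 3)
  expect_equal(length(unique(g$regulator)), 2)

  readr::write_tsv(tibble::tibble(
    regulator = c("A", "A", "A"), target = c("B", "B", "A")), tmp)
  expect_warning(g2 <- read_grn(tmp), "duplicate")
  expect_equal(nrow(g2), 2)
  expect_equal(attr(g2, "n_self_edges"), 1)

  readr::write_tsv(tibble::tibble(reg = "A", tar = "B"), tmp)
  expect_error(read_grn(tmp), "regulator")
})

test_that("degrees are exact and conserve the edge count", {
  g <- grn_edges(tibble::tibble(regulator = c("A", "A", "B"),
                                target = c("B", "C", "C")))
  deg <- grn_degrees(g)
  expect_equal(deg$out_degree[deg$gene_id == "A"], 2L)
  expect_equal(deg$in_degree[deg$gene_id == "C"], 2L)
  expect_equal(deg$out_degree[deg$gene_id == "C"], 0L)
  expect_true(deg$is_regulator[deg$gene_id == "A"])

  hub <- grn_edges(tibble::tibble(regulator = "hub",
                                  target = paste0("leaf", 1:10)))
  dh <- grn_degrees(hub)
  expect_equal(dh$out_degree[dh$gene_id == "hub"], 10L)
  expect_true(all(dh$in_degree[dh$gene_id != "hub"] == 1L))

  # conservation on random generated graphs
  for (s in 1:5) {
    gr <- simulate_grn(20, 100, mean_out_degree = 5, self_edge_rate = 0.2,
                       seed = s)
    dd <- grn_degrees(gr)
    expect_equal(sum(dd$out_degree), nrow(gr))
    expect_equal(sum(dd$in_degree), nrow(gr))
  }
})

test_that("induced sub-network keeps edges with both endpoints in the set", {
  g <- grn_edges(tibble::tibble(regulator = c("A", "B", "C"),
                                target = c("B", "C", "D")))
  sub <- extract_subnetwork(g, c("A", "B", "C"))
  expect_equal(nrow(sub), 2)
  part <- attr(sub, "partition")
  expect_equal(part$n_regulators, 2)
  expect_equal(part$n_targets, 1)

  expect_warning(empty <- extract_subnetwork(g, c("X", "Y")), "no edge")
  expect_equal(nrow(empty), 0)

  all_sub <- extract_subnetwork(g, c("A", "B", "C", "D"))
  expect_equal(nrow(all_sub), nrow(g))

  # monotonicity: growing the gene set never removes edges
  set.seed(7)
  gr <- simulate_grn(10, 50, seed = 2)
  nodes <- unique(c(gr$regulator, gr$target))
  small <- sample(nodes, 20)
  big <- union(small, sample(nodes, 20))
  e_small <- suppressWarnings(extract_subnetwork(gr, small))
  e_big <- suppressWarnings(extract_subnetwork(gr, big))
  expect_true(nrow(e_big) >= nrow(e_small))
  expect_equal(nrow(dplyr::anti_join(e_small, e_big,
                                     by = c("regulator", "target"))), 0)
})

test_that("connectivity correlations recover planted monotone structure", {
  # perfect monotone decrease -> spearman rho = -1
  deg <- tibble::tibble(gene_id = paste0("g", 1:10),
                        out_degree = 1:10, in_degree = 1:10,
                        is_regulator = TRUE)
  de <- tibble::tibble(transcript_id = paste0("g", 1:10),
                       log2FC = seq(2, 0.2, length.out = 10))
  ga <- tibble::tibble(transcript_id = paste0("g", 1:10),
                       k = seq(3, 0.5, length.out = 10))
  res <- connectivity_correlations(deg, de, ga)
  sp <- res[res$method == "spearman", ]
  expect_equal(sp$estimate, rep(-1, 4))

  # zero variance flagged as NA
  ga2 <- dplyr::mutate(ga, k = 1)
  res2 <- connectivity_correlations(deg, de, ga2)
  expect_true(all(is.na(
    res2$estimate[res2$response == "abs_k" & res2$method == "spearman"])))

  # spearman equals rank-then-pearson on a 6-point fixture
  x <- c(3, 1, 4, 1.5, 9, 2.6); y <- c(2, 7, 1, 8, 2.8, 1.8)
  deg6 <- tibble::tibble(gene_id = paste0("h", 1:6), out_degree = x,
                         in_degree = x, is_regulator = TRUE)
  de6 <- tibble::tibble(transcript_id = paste0("h", 1:6), log2FC = y)
  ga6 <- tibble::tibble(transcript_id = paste0("h", 1:6), k = y)
  r6 <- connectivity_correlations(deg6, de6, ga6)
  manual <- cor(rank(x), rank(y))
  expect_equal(
    r6$estimate[r6$response == "abs_lfc" & r6$predictor == "out_degree" &
                  r6$method == "spearman"], manual)
  expect_error(connectivity_correlations(deg[1:2, ], de, ga), "fewer than 3")
})

test_that("divergence decreasing in out-degree is detected at n = 500", {
  set.seed(13)
  n <- 500
  outd <- sample(1:50, n, replace = TRUE)
  lfc <- 2 - 0.02 * outd + rnorm(n, 0, 0.3)
  deg <- tibble::tibble(gene_id = paste0("g", 1:n), out_degree = outd,
                        in_degree = sample(1:10, n, TRUE),
                        is_regulator = TRUE)
  de <- tibble::tibble(transcript_id = paste0("g", 1:n), log2FC = lfc)
  ga <- tibble::tibble(transcript_id = paste0("g", 1:n), k = rnorm(n, 0, 1))
  res <- connectivity_correlations(deg, de, ga)
  row <- res[res$response == "abs_lfc" & res$predictor == "out_degree" &
               res$method == "spearman", ]
  expect_lt(row$estimate, 0)
  expect_lt(row$pvalue, 0.05)
})

test_that("loess curve reproduces linear and constant signals exactly", {
  x <- seq(0, 10, length.out = 30)
  lin <- loess_curve(x, 2 * x + 1)
  expect_lt(max(abs(lin$fitted - (2 * lin$x + 1))), 1e-8)
  const <- loess_curve(x, rep(3, 30))
  expect_lt(max(abs(const$fitted - 3)), 1e-10)
  expect_error(loess_curve(1:5, 1:5), "at least 10")

  # noisy quadratic: fitted curve stays within the noise envelope
  set.seed(17)
  xq <- runif(300, -1, 1)
  yq <- xq^2 + rnorm(300, 0, 0.2)
  fit <- loess_curve(xq, yq, span = 0.75)
  rmse <- sqrt(mean((fit$fitted - fit$x^2)^2))
  expect_lt(rmse, 0.2)
})
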