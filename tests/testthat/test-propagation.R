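test_that("edge similarity follows its closed form and floor guard", {
  expect_equal(edge_similarity(0.8, 0.8), 0)
  expect_equal(edge_similarity(1.0, 0.25), 2)
  expect_equal(edge_similarity(-1.0, 1.0), 0)  # absolute-value convention
  expect_true(is.na(edge_similarity(1.0, 0)))
  expect_true(is.na(edge_similarity(1.0, 5e-4)))  # below default floor

  # symmetry and s(k, c*k) = |log2 c|
  set.seed(3)
  ks <- runif(20, 0.1, 3) * sample(c(-1, 1), 20, TRUE)
  for (c0 in c(0.25, 0.5, 1, 2, 8)) {
    expect_equal(edge_similarity(ks, c0 * ks), rep(abs(log2(c0)), 20))
    expect_equal(edge_similarity(ks, c0 * ks),
                 edge_similarity(c0 * ks, ks))
  }
})

test_that("edge similarity tables exclude self-edges and floored k", {
  grn <- grn_edges(tibble::tibble(
    regulator = c("R1", "R1", "R2", "R2"),
    target = c("T1", "T2", "T3", "R2")))
  ga <- tibble::tibble(
    transcript_id = c("R1", "R2", "T1", "T2", "T3"),
    k = c(1, 0.5, 0.5, 1e-5, NA),
    category = classify_gene_action(c(1, 0.5, 0.5, 1e-5, NA)))
  est <- edge_similarity_table(grn, ga)
  expect_equal(nrow(est), 1)  # T2 floored, T3 undefined, R2->R2 self
  expect_equal(est$s, 1)      # |log2(1 / 0.5)|
  expect_equal(attr(est, "n_self_edges"), 1)
  expect_equal(attr(est, "n_excluded"), 2)
})

test_that("median similarity is grouped by regulator category", {
  est <- tibble::tibble(
    regulator = c("R1", "R1", "R1", "R2"),
    target = paste0("T", 1:4),
    k_reg = c(1, 1, 1, 0.1), k_tar = c(0.5, 0.25, 0.125, 0.1),
    s = c(1, 2, 3, 0), sign_discordant = FALSE,
    reg_category = c("dominant_recessive", "dominant_recessive",
                     "dominant_recessive", "additive"),
    tar_category = "additive")
  bycat <- similarity_by_regulator_category(est)
  expect_equal(
    bycat$median_s[bycat$reg_category == "dominant_recessive"], 2)
  expect_equal(bycat$median_s[bycat$reg_category == "additive"], 0)

  # all-identical k -> every group median 0
  est0 <- dplyr::mutate(est, s = 0)
  expect_true(all(similarity_by_regulator_category(est0)$median_s == 0))
})

test_that("pairwise Wilcoxon matches exhaustive enumeration", {
  r <- pairwise_wilcoxon(c(1, 2, 3, 4, 5, 6),
                         rep(c("a", "b"), each = 3))
  expect_equal(r$pvalue, 0.1)  # {1,2,3} vs {4,5,6}, exact
  expect_equal(r$pvalue, brute_wilcox_p(1:3, 4:6))

  ident <- pairwise_wilcoxon(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))
  expect_equal(ident$pvalue, 1)
  expect_equal(ident$effect_r, 0)

  # sweep: all group sizes with n1 + n2 <= 10, continuous values
  set.seed(9)
  for (n1 in 2:5) for (n2 in 2:5) {
    if (n1 + n2 > 10) next
    v <- rnorm(n1 + n2)
    got <- pairwise_wilcoxon(v, rep(c("a", "b"), c(n1, n2)))$pvalue
    expect_equal(got, brute_wilcox_p(v[seq_len(n1)], v[-seq_len(n1)]))
  }

  # complete separation at 10 + 10: effect size near its maximum
  sep <- pairwise_wilcoxon(c(1:10, 101:110), rep(c("a", "b"), each = 10))
  z_max <- abs(qnorm(brute_wilcox_p(1:10, 101:110) / 2))
  expect_equal(sep$effect_r, z_max / sqrt(20))
  expect_gt(sep$effect_r, 0.8)

  expect_warning(
    pairwise_wilcoxon(c(1, 2, 3, 4), c("a", "a", "a", "b")), "skipping")
})

test_that("binomial deficit test matches the exact tail", {
  expect_equal(regulator_target_binomial(0, 4, 0.5)$pvalue, 0.0625)
  # observed at the null expectation -> one-sided p > 0.5
  expect_gt(regulator_target_binomial(2, 4, 0.5)$pvalue, 0.5)
  # echoes p0 and matches pbinom for an arbitrary case
  r <- regulator_target_binomial(3, 24, 0.22)
  expect_equal(r$p0, 0.22)
  expect_equal(r$pvalue, pbinom(3, 24, 0.22))
  expect_error(regulator_target_binomial(1, 4, 1.2), "between 0 and 1")
  expect_error(regulator_target_binomial(5, 4, 0.5), "n_observed")
})

test_that("dominance-rule networks show higher similarity than null", {
  grn <- simulate_grn(40, 200, mean_out_degree = 5, seed = 101)
  regs <- unique(grn$regulator)
  withr::with_seed(202, {
    reg_k <- setNames(runif(length(regs), 0.3, 3) *
                        sample(c(-1, 1), length(regs), TRUE), regs)
  })
  dom <- propagate_gene_action(grn, reg_k, "dominance", noise_sd = 0.1,
                               seed = 303)
  ind <- propagate_gene_action(grn, reg_k, "independent", seed = 303)
  est_d <- edge_similarity_table(grn, k_assignment_as_gene_action(dom$k))
  est_i <- edge_similarity_table(grn, k_assignment_as_gene_action(ind$k))
  expect_lt(median(est_d$s), median(est_i$s))

  # permutation destroys the dominance signal
  withr::with_seed(404, {
    perm <- dom$k
    tar <- perm$role == "target"
    perm$k[tar] <- sample(perm$k[tar])
  })
  est_p <- edge_similarity_table(grn, k_assignment_as_gene_action(perm))
  expect_lt(median(est_d$s), median(est_p$s))
})

test_that("dominant regulators propagate more faithfully than additive", {
  grn <- simulate_grn(60, 300, mean_out_degree = 5, seed = 11)
  regs <- unique(grn$regulator)
  withr::with_seed(12, {
    reg_k <- setNames(geneaction:::draw_k(length(regs),
                                          default_k_mixture()), regs)
  })
  prop <- propagate_gene_action(grn, reg_k, "beneficial_allele",
                                noise_sd = 0.1, seed = 13)
  est <- edge_similarity_table(grn, k_assignment_as_gene_action(prop$k))
  bycat <- similarity_by_regulator_category(est)
  med <- setNames(bycat$median_s, as.character(bycat$reg_category))
  expect_lt(med[["dominant_recessive"]], med[["additive"]])
})

test_that("annotated networks round-trip through GraphML", {
  grn <- grn_edges(tibble::tibble(regulator = c("R1", "R2"),
                                  target = c("T1", "T2")))
  ga <- tibble::tibble(transcript_id = c("R1", "R2", "T1"),
                       k = c(1, 0.5, 0.5),
                       category = classify_gene_action(c(1, 0.5, 0.5)))
  est <- edge_similarity_table(grn, ga)
  tmp <- withr::local_tempfile(fileext = ".graphml")
  export_annotated_network(grn, est, ga, tmp)
  g <- igraph::read_graph(tmp, format = "graphml")
  vc <- setNames(igraph::V(g)$category, igraph::V(g)$name)
  expect_equal(vc[["R1"]], "dominant_recessive")
  expect_equal(vc[["T2"]], "undefined")  # node without k
  s_attr <- igraph::E(g)$s
  expect_equal(sort(is.na(s_attr)), c(FALSE, TRUE))  # excluded edge marked
  expect_true(file.exists(sub("\\.graphml$", ".tsv", tmp)))
})
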