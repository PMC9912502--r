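#' Default gene-action category mixture for simulations
#'
#' Category weights follow the composition observed for trans-acting
#' regulators in an Arabidopsis Col x C24 cross (additive 14.6%, partially
#' dominant 26.6%, dominant-recessive 24.8%, transgressive 34.0%); |k| is
#' drawn uniformly within each category band (transgressive capped at
#' `k_max`) with a random sign.
#'
#' @param boundaries category boundaries (see [classify_gene_action()]).
#' @param k_max upper bound on simulated |k| (default 3).
#' @return tibble with columns `category`, `weight`, `k_lo`, `k_hi`.
#' @export
default_k_mixture <- function(boundaries = c(0.25, 0.75, 1.25), k_max = 3) {
  tibble(category = GA_CATEGORIES[1:4],
         weight = c(0.146, 0.266, 0.248, 0.340),
         k_lo = c(0, boundaries),
         k_hi = c(boundaries, k_max))
}

draw_k <- function(n, k_mixture) {
  idx <- sample.int(nrow(k_mixture), n, replace = TRUE,
                    prob = k_mixture$weight)
  mag <- runif(n, k_mixture$k_lo[idx], k_mixture$k_hi[idx])
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Simulate a parent/parent/F1 cross with known ground truth
#'
#' Generates negative-binomial counts for the two F0 parents and their F1
#' hybrid. A fraction `de_fraction` of genes is differentially expressed
#' between the parents with `|log2FC|` uniform in `[lfc_min, lfc_max]`
#' (random direction); the rest have identical parental means. Every gene
#' carries a true degree of dominance drawn from `k_mixture`, and the true
#' F1 mean is the linear gene-action model
#' `midparent + k * (mu1 - mu2) / 2`. Genes whose F1 mean would be
#' negative are redrawn (up to 100 times; the event count is recorded).
#' Per-sample library-size factors are log-normal with sdlog
#' `lib_size_spread`, and counts are `NB(mean * factor, dispersion)`.
#' The generator is a pure function of its parameters and `seed`.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_reps replicates per role (default 3).
#' @param de_fraction fraction of DE genes (default 0.35, the average DE
#'   fraction seen in domesticated-wild crosses).
#' @param k_mixture tibble from [default_k_mixture()].
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline expression mean (defaults `log(100)`, 1).
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`;
#'   default 0.05, a typical inter-replicate value for RNA-seq).
#' @param lib_size_spread sdlog of the per-sample library-size factors
#'   (default 0.1).
#' @param lfc_min,lfc_max bounds of `|log2FC|` for DE genes (defaults 1
#'   and 3).
#' @param seed integer seed; same seed, same output.
#' @return object of class `sim_cross`: list with `counts` (a
#'   [count_matrix()]), `truth` (tibble: `transcript_id`, `mu1`, `mu2`,
#'   `mu_f1`, `true_log2FC`, `true_k`, `true_category`, `is_DE_true`),
#'   `params` (list, including `n_redraws`).
#' @export
simulate_cross <- function(n_genes = 2000, n_reps = 3, de_fraction = 0.35,
                           k_mixture = default_k_mixture(),
                           baseline_meanlog = log(100), baseline_sdlog = 1,
                           dispersion = 0.05, lib_size_spread = 0.1,
                           lfc_min = 1, lfc_max = 3, seed = 1) {
  stopifnot(abs(sum(k_mixture$weight) - 1) < 1e-8, dispersion > 0,
            de_fraction >= 0, de_fraction <= 1, lfc_min <= lfc_max)
  withr::with_seed(seed, {
    base <- exp(rnorm(n_genes, baseline_meanlog, baseline_sdlog))
    is_de <- seq_len(n_genes) <= round(de_fraction * n_genes)
    n_redraws <- 0L

    draw_gene <- function(b, de) {
      for (i in 1:100) {
        lfc <- if (de) runif(1, lfc_min, lfc_max) * sample(c(-1, 1), 1) else 0
        k <- draw_k(1, k_mixture)
        mu1 <- b * 2^(lfc / 2); mu2 <- b * 2^(-lfc / 2)
        muf <- (mu1 + mu2) / 2 + k * (mu1 - mu2) / 2
        if (muf >= 0) return(c(mu1, mu2, muf, lfc, k, i - 1))
      }
      abort("simulate_cross: failed to draw a non-negative F1 mean in 100 tries")
    }
    par_mat <- t(vapply(seq_len(n_genes),
                        function(i) draw_gene(base[i], is_de[i]),
                        numeric(6)))
    n_redraws <- as.integer(sum(par_mat[, 6]))

    ids <- sprintf("gene_%05d", seq_len(n_genes))
    roles <- rep(c("parent1", "parent2", "F1"), each = n_reps)
    sample_ids <- paste0(rep(c("P1", "P2", "F1"), each = n_reps), "_",
                         rep(seq_len(n_reps), 3))
    sf <- exp(rnorm(length(roles), 0, lib_size_spread))
    mu_by_role <- cbind(parent1 = par_mat[, 1], parent2 = par_mat[, 2],
                        F1 = par_mat[, 3])
    counts <- vapply(seq_along(roles), function(j) {
      rnbinom(n_genes, mu = mu_by_role[, roles[j]] * sf[j],
              size = 1 / dispersion)
    }, numeric(n_genes))
    dimnames(counts) <- list(ids, sample_ids)

    samples <- tibble(sample_id = sample_ids, cross_id = "sim_cross",
                      role = roles, replicate = rep(seq_len(n_reps), 3))
    truth <- tibble(transcript_id = ids, mu1 = par_mat[, 1],
                    mu2 = par_mat[, 2], mu_f1 = par_mat[, 3],
                    true_log2FC = par_mat[, 4], true_k = par_mat[, 5],
                    true_category = classify_gene_action(par_mat[, 5]),
                    is_DE_true = is_de)
    structure(list(counts = count_matrix(counts, samples), truth = truth,
                   params = list(n_genes = n_genes, n_reps = n_reps,
                                 de_fraction = de_fraction,
                                 dispersion = dispersion,
                                 lib_size_spread = lib_size_spread,
                                 lfc_min = lfc_min, lfc_max = lfc_max,
                                 seed = seed, n_redraws = n_redraws)),
              class = "sim_cross")
  })
}

#' @export
glance.sim_cross <- function(x, ...) {
  tibble(n_genes = x$params$n_genes, n_reps = x$params$n_reps,
         n_de_true = sum(x$truth$is_DE_true),
         n_redraws = x$params$n_redraws, seed = x$params$seed)
}

#' Simulate a directed regulator-target network
#'
#' Builds a bipartite regulator-to-target graph (plus optional self-edges
#' on regulators). Out-degrees follow either a discrete uniform law with
#' the given mean or a discretized power law (density exponent
#' `powerlaw_exponent`, so the tail CCDF falls as
#' `x^-(powerlaw_exponent - 1)`), capped at `n_targets`; each regulator's
#' targets are sampled without replacement.
#'
#' @param n_regulators,n_targets node counts.
#' @param mean_out_degree mean out-degree for the uniform law (default 4).
#' @param degree_law `"uniform"` or `"powerlaw"`.
#' @param powerlaw_exponent density exponent for the power law
#'   (default 2.5).
#' @param self_edge_rate probability a regulator also regulates itself
#'   (default 0).
#' @param seed integer seed.
#' @return edge-list tibble (columns `regulator`, `target`) as from
#'   [grn_edges()].
#' @export
simulate_grn <- function(n_regulators, n_targets, mean_out_degree = 4,
                         degree_law = c("uniform", "powerlaw"),
                         powerlaw_exponent = 2.5, self_edge_rate = 0,
                         seed = 1) {
  degree_law <- match.arg(degree_law)
  stopifnot(n_regulators >= 1, n_targets >= 1, mean_out_degree >= 1)
  if (mean_out_degree > n_targets)
    abort("mean_out_degree cannot exceed n_targets")
  withr::with_seed(seed, {
    regs <- sprintf("reg_%04d", seq_len(n_regulators))
    tars <- sprintf("tar_%05d", seq_len(n_targets))
    deg <- if (degree_law == "uniform") {
      sample.int(2 * mean_out_degree - 1, n_regulators, replace = TRUE)
    } else {
      u <- runif(n_regulators)
      pmin(floor(u^(-1 / (powerlaw_exponent - 1))), n_targets)
    }
    edges <- purrr::map(seq_len(n_regulators), function(i) {
      tibble(regulator = regs[i],
             target = sample(tars, deg[i], replace = FALSE))
    }) |> bind_rows()
    selfs <- regs[runif(n_regulators) < self_edge_rate]
    if (length(selfs) > 0)
      edges <- bind_rows(edges, tibble(regulator = selfs, target = selfs))
    grn_edges(edges)
  })
}

#' Propagate gene action from regulators to targets
#'
#' Assigns a true degree of dominance to every target of a network from
#' its regulators' k under one of three generative rules:
#' \describe{
#'   \item{`dominance`}{`k_TAR = k_REG(primary) + N(0, noise_sd)`: the
#'     regulator's mode of action is transmitted to its targets.}
#'   \item{`beneficial_allele`}{targets of additive regulators
#'     (`|k_REG| < 0.25`) become transgressive (`|k_TAR|` uniform in
#'     `[1.25, 3]`, random sign) — the two functional regulator alleles
#'     act cumulatively; targets of non-additive regulators follow the
#'     dominance rule.}
#'   \item{`independent`}{`k_TAR` resampled from the marginal regulator-k
#'     distribution, ignoring the network: the no-propagation null.}
#' }
#' A target with several regulators uses the regulator with the highest
#' out-degree as primary (ties broken lexicographically by id). Self-edges
#' are ignored for propagation.
#'
#' @param grn edge-list tibble.
#' @param regulator_k named numeric vector of regulator k values (names =
#'   regulator ids, must cover every regulator in `grn`).
#' @param rule `"dominance"`, `"beneficial_allele"` or `"independent"`.
#' @param noise_sd SD of the propagation noise (default 0.1).
#' @param seed integer seed.
#' @return list with `k` (tibble: `gene_id`, `k`, `role`, covering
#'   regulators and targets — the input to [edge_similarity_table()] after
#'   renaming), and `truth` (tibble: `target`, `primary_regulator`,
#'   `rule`, `k_target`).
#' @export
propagate_gene_action <- function(grn, regulator_k,
                                  rule = c("dominance", "beneficial_allele",
                                           "independent"),
                                  noise_sd = 0.1, seed = 1) {
  rule <- match.arg(rule)
  edges <- filter(grn, .data$regulator != .data$target)
  regs <- unique(edges$regulator)
  missing_k <- setdiff(regs, names(regulator_k))
  if (length(missing_k) > 0)
    abort(paste0("regulator(s) without k: ",
                 paste(head(missing_k, 5), collapse = ", ")))
  targets <- setdiff(unique(grn$target), grn$regulator)
  unreachable <- setdiff(targets, edges$target)
  if (length(unreachable) > 0)
    abort(paste0("target(s) with no regulator: ",
                 paste(head(unreachable, 5), collapse = ", ")))
  outd <- table(factor(edges$regulator, levels = regs))

  primary <- edges |>
    filter(.data$target %in% targets) |>
    mutate(outd = as.integer(outd[.data$regulator])) |>
    arrange(.data$target, dplyr::desc(.data$outd), .data$regulator) |>
    group_by(.data$target) |>
    dplyr::slice(1) |>
    ungroup()

  withr::with_seed(seed, {
    kp <- unname(regulator_k[primary$regulator])
    n <- nrow(primary)
    k_tar <- switch(rule,
      dominance = kp + rnorm(n, 0, noise_sd),
      beneficial_allele = {
        add <- abs(kp) < 0.25
        out <- kp + rnorm(n, 0, noise_sd)
        out[add] <- runif(sum(add), 1.25, 3) *
          sample(c(-1, 1), sum(add), replace = TRUE)
        out
      },
      independent = sample(unname(regulator_k), n, replace = TRUE))
    k_tab <- bind_rows(
      tibble(gene_id = names(regulator_k),
             k = unname(regulator_k), role = "regulator"),
      tibble(gene_id = primary$target, k = k_tar, role = "target"))
    list(k = k_tab,
         truth = tibble(target = primary$target,
                        primary_regulator = primary$regulator,
                        rule = rule, k_target = k_tar))
  })
}

#' Gene-action tibble from a simulated k assignment
#'
#' Convenience wrapper shaping the `k` table of
#' [propagate_gene_action()] like a [gene_action_table()] output so it can
#' feed [edge_similarity_table()].
#'
#' @param k_tab tibble with `gene_id` and `k`.
#' @param cross_id label for the simulated cross.
#' @return tibble with `cross_id`, `transcript_id`, `k`, `category`.
#' @export
k_assignment_as_gene_action <- function(k_tab, cross_id = "sim") {
  tibble(cross_id = cross_id, transcript_id = k_tab$gene_id, k = k_tab$k,
         category = classify_gene_action(k_tab$k))
}
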