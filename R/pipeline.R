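#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, applies documented defaults, range-checks
#' every threshold and rejects unknown keys. Recognised keys:
#' `counts`, `samples` (required input paths), `grn`, `go_map` (optional
#' paths), `regimes` (mapping cross_id -> regime), `alpha` (FDR threshold,
#' (0, 1]), `lfc_min` (>= 0), `min_median` (>= 0), `category_boundaries`
#' (three increasing positives), `k_floor` (>= 0), `a_tol` (> 0),
#' `correlation_method` (`spearman`/`pearson`), `go_terms`, `seed`
#' (integer), `outdir` (required).
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
validate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("counts", "samples", "grn", "go_map", "regimes", "alpha",
             "lfc_min", "min_median", "category_boundaries", "k_floor",
             "a_tol", "correlation_method", "go_terms", "seed", "outdir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  for (req in c("counts", "samples", "outdir"))
    if (is.null(cfg[[req]]))
      abort(paste0("config is missing required key '", req, "'"))

  defaults <- list(alpha = 0.05, lfc_min = 0.5, min_median = 5,
                   category_boundaries = c(0.25, 0.75, 1.25),
                   k_floor = 1e-3, a_tol = 1e-8,
                   correlation_method = "spearman", seed = 1,
                   go_terms = names(domestication_go_terms()))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]

  check <- function(cond, key, msg)
    if (!cond) abort(sprintf("config key '%s': %s", key, msg))
  check(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha <= 1,
        "alpha", "must be in (0, 1]")
  check(is.numeric(cfg$lfc_min) && cfg$lfc_min >= 0, "lfc_min",
        "must be >= 0")
  check(is.numeric(cfg$min_median) && cfg$min_median >= 0, "min_median",
        "must be >= 0")
  cb <- as.numeric(cfg$category_boundaries)
  check(length(cb) == 3 && all(cb > 0) && all(diff(cb) > 0),
        "category_boundaries", "must be three strictly increasing positives")
  cfg$category_boundaries <- cb
  check(is.numeric(cfg$k_floor) && cfg$k_floor >= 0, "k_floor",
        "must be >= 0")
  check(is.numeric(cfg$a_tol) && cfg$a_tol > 0, "a_tol", "must be > 0")
  check(cfg$correlation_method %in% c("spearman", "pearson"),
        "correlation_method", "must be 'spearman' or 'pearson'")
  check(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed",
        "must be an integer")
  cfg
}

#' Run the full inheritance-of-abundance pipeline
#'
#' Executes, in order: count loading, median filter, parent-vs-parent NB
#' Wald differential abundance, gene-action estimation, regime comparison
#' (when `regimes` covers more than one regime), GRN connectivity and
#' propagation (when a `grn` path is configured) and GO
#' presence/enrichment (when a `go_map` is configured). Each stage's table
#' is written as TSV under `outdir`, plus `manifest.json` recording the
#' config, package version, input checksums and per-stage row counts.
#' Identical config and inputs give byte-identical stage outputs.
#'
#' @param config validated config list from [validate_config()], or a path
#'   to a YAML file.
#' @return the output directory path, invisibly; stage results are also
#'   returned as the attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  res <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
  }

  cm <- stage("read_counts", read_counts(config$counts, config$samples))
  cm <- stage("filter_low",
              suppressMessages(filter_low(cm, config$min_median)))

  de <- stage("de_test",
              de_test(cm, alpha = config$alpha, lfc_min = config$lfc_min))
  write_de_table(de, out("de_table.tsv"))
  res$de <- de

  ga <- stage("gene_action", suppressMessages(
    gene_action_table(de, a_tol = config$a_tol,
                      boundaries = config$category_boundaries)))
  write_gene_action(ga, out("gene_action.tsv"))
  res$gene_action <- ga

  if (!is.null(config$regimes)) {
    regimes <- unlist(config$regimes)
    pooled <- stage("pool_k", suppressMessages(pool_k(ga, regimes)))
    res$pooled <- pooled
    if (length(unique(pooled$regime)) >= 2) {
      cmp <- stage("compare_regimes", compare_regimes(pooled))
      readr::write_tsv(cmp$ks, out("regime_ks.tsv"), progress = FALSE)
      readr::write_tsv(cmp$additive_fraction,
                       out("regime_additive_fraction.tsv"), progress = FALSE)
      res$compare <- cmp
    }
    summ <- stage("regime_summary", regime_summary(pooled))
    readr::write_tsv(summ$proportions, out("regime_proportions.tsv"),
                     progress = FALSE)
  }

  if (!is.null(config$grn)) {
    grn <- stage("read_grn", read_grn(config$grn))
    deg <- grn_degrees(grn)
    readr::write_tsv(deg, out("grn_degrees.tsv"), progress = FALSE)
    de_genes <- unique(de$transcript_id[de$is_DE])
    sub <- stage("extract_subnetwork",
                 suppressWarnings(extract_subnetwork(grn, de_genes)))
    cors <- stage("connectivity_correlations",
                  connectivity_correlations(deg, de, ga,
                                            method = config$correlation_method))
    readr::write_tsv(cors, out("connectivity_correlations.tsv"),
                     progress = FALSE)
    res$correlations <- cors
    est <- stage("edge_similarity",
                 edge_similarity_table(grn, ga, k_floor = config$k_floor))
    readr::write_tsv(est, out("edge_similarity.tsv"), progress = FALSE)
    res$similarity <- est
    if (nrow(est) > 0) {
      bycat <- similarity_by_regulator_category(est)
      readr::write_tsv(bycat, out("similarity_by_category.tsv"),
                       progress = FALSE)
      ok <- table(est$reg_category)
      if (sum(ok >= 2) >= 2) {
        wt <- pairwise_wilcoxon(est$s, est$reg_category)
        readr::write_tsv(wt, out("similarity_wilcoxon.tsv"),
                         progress = FALSE)
        res$wilcoxon <- wt
      }
      export_annotated_network(if (nrow(sub) > 0) sub else grn, est, ga,
                               out("annotated_network.graphml"))
    }
  }

  if (!is.null(config$go_map)) {
    gomap <- stage("read_go_map", read_go_map(config$go_map))
    enr <- stage("category_enrichment",
                 category_enrichment(ga, gomap, terms = config$go_terms))
    readr::write_tsv(enr, out("enrichment.tsv"), progress = FALSE)
    res$enrichment <- enr
  }

  manifest <- list(
    config = config,
    package_version = as.character(utils::packageVersion("geneaction")),
    input_md5 = as.list(tools::md5sum(
      unlist(config[c("counts", "samples", "grn", "go_map")],
             use.names = FALSE))),
    stage_rows = purrr::map(res, function(x)
      if (is.data.frame(x)) nrow(x) else NA_integer_))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  ret <- config$outdir
  attr(ret, "results") <- res
  invisible(ret)
}
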