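#' Read a gene-to-GO mapping
#'
#' TSV with two columns: `gene_id` and a semicolon-separated list of GO
#' term ids (`GO:` followed by seven digits). An empty annotation field
#' yields a gene with an empty term set; any malformed term id aborts with
#' the offending line number.
#'
#' @param path TSV path (header required).
#' @return tibble with columns `gene_id`, `go_id` (one row per
#'   gene-term pair; genes with no terms are retained with `NA` `go_id`).
#' @export
read_go_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!"gene_id" %in% names(tab) || ncol(tab) < 2)
    abort("GO map needs a 'gene_id' column and an annotation column")
  ann <- tab[[setdiff(names(tab), "gene_id")[1]]]
  terms <- strsplit(ifelse(is.na(ann), "", ann), ";", fixed = TRUE)
  for (i in seq_along(terms)) {
    tm <- trimws(terms[[i]])
    tm <- tm[tm != ""]
    bad <- tm[!grepl("^GO:[0-9]{7}$", tm)]
    if (length(bad) > 0)
      abort(sprintf("malformed GO id '%s' on line %d", bad[1], i + 1L))
    terms[[i]] <- tm
  }
  tibble(gene_id = rep(tab$gene_id, lengths(terms) + (lengths(terms) == 0)),
         go_id = unlist(purrr::map(terms, function(t)
           if (length(t) == 0) NA_character_ else t)))
}

#' The five domestication-syndrome GO terms used by default
#'
#' Cell cycle, cell fate determination, flower development, response to
#' auxin and seed dormancy: the biological processes most directly tied to
#' the domestication syndrome (organ gigantism, altered flowering, reduced
#' dormancy).
#'
#' @return named character vector of GO ids.
#' @export
domestication_go_terms <- function() {
  c("GO:0007049" = "cell cycle",
    "GO:0001709" = "cell fate determination",
    "GO:0009909" = "flower development",
    "GO:0009733" = "response to auxin",
    "GO:0009793" = "seed dormancy")
}

#' Hypergeometric GO presence/enrichment per gene-action category
#'
#' For every cross, gene-action category and GO term, tests
#' over-representation of the term among the category's genes relative to
#' the universe (by default all transcripts of the cross present in the
#' gene-action table that carry at least one GO annotation) with a
#' one-sided hypergeometric test, BH-adjusted across terms within each
#' (cross, category). `present` records whether the term annotates at
#' least one category gene regardless of significance — with small
#' categories the test has little power, so presence is reported in its
#' own right. A term absent from the universe yields `p = 1`.
#'
#' @param ga gene-action tibble from [gene_action_table()].
#' @param go_map tibble from [read_go_map()].
#' @param terms character vector of GO ids to test (default
#'   [domestication_go_terms()]).
#' @return tibble: `cross_id`, `category`, `go_id`,
#'   `n_annotated_in_category`, `n_category`, `n_annotated_in_universe`,
#'   `n_universe`, `pvalue`, `padj`, `present`, `method`.
#' @export
category_enrichment <- function(ga, go_map,
                                terms = names(domestication_go_terms())) {
  go <- filter(go_map, !is.na(.data$go_id))
  purrr::map(unique(ga$cross_id), function(cr) {
    sub <- filter(ga, .data$cross_id == cr)
    universe <- intersect(sub$transcript_id, unique(go$gene_id))
    n_univ <- length(universe)
    cats <- setdiff(unique(as.character(sub$category)), "undefined")
    purrr::map(cats, function(cat) {
      cat_genes <- intersect(
        sub$transcript_id[as.character(sub$category) == cat], universe)
      n_cat <- length(cat_genes)
      rows <- purrr::map(terms, function(tm) {
        term_genes <- intersect(go$gene_id[go$go_id == tm], universe)
        m_t <- length(term_genes)
        q <- length(intersect(cat_genes, term_genes))
        p <- if (m_t == 0 || n_univ == 0) 1 else
          phyper(q - 1, m_t, n_univ - m_t, n_cat, lower.tail = FALSE)
        tibble(cross_id = cr, category = cat, go_id = tm,
               n_annotated_in_category = q, n_category = n_cat,
               n_annotated_in_universe = m_t, n_universe = n_univ,
               pvalue = p, present = q >= 1)
      }) |> bind_rows()
      mutate(rows, padj = p.adjust(.data$pvalue, method = "BH"),
             method = "hypergeometric-classic")
    }) |> bind_rows()
  }) |> bind_rows()
}
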