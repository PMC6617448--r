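# Gene-set over-representation (hypergeometric, shared core with the hub
# statistic) and Jaccard term-crosstalk edges.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return long tibble `term_id`, `term_name`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]))
  }
  dplyr::bind_rows(map(fields, function(f) {
    tibble(term_id = f[1], term_name = f[2], gene = unique(f[-(1:2)]))
  }))
}

as_gene_sets <- function(gene_sets) {
  if (is.data.frame(gene_sets)) {
    need <- c("term_id", "gene")
    if (!all(need %in% names(gene_sets))) {
      abort("gene_sets data frame needs columns term_id, gene (term_name optional)")
    }
    if (!"term_name" %in% names(gene_sets)) gene_sets$term_name <- gene_sets$term_id
    return(gene_sets |> distinct(.data$term_id, .data$term_name, .data$gene))
  }
  if (is.list(gene_sets)) {
    nm <- names(gene_sets) %||% abort("gene_sets list must be named")
    return(dplyr::bind_rows(imap(gene_sets, function(g, id) {
      tibble(term_id = id, term_name = id, gene = unique(as.character(g)))
    })))
  }
  abort("gene_sets must be a long data frame or a named list of gene vectors")
}

#' Gene-set over-representation analysis
#'
#' Per term, the p-value is the hypergeometric enrichment tail
#' `P(X >= k)` for `k` query hits in a set of size `K`, with a query of
#' size `n` drawn from a universe of `N` genes; BH FDR across terms.
#' Query genes outside the universe are dropped with a message, and each
#' term is restricted to the universe before counting.
#'
#' @param query character vector of genes (e.g. confirmed EI genes).
#' @param gene_sets long tibble (`term_id`, `term_name`, `gene`), a
#'   named list of gene vectors, or the output of [read_gmt()].
#' @param universe background gene vector; defaults to the union of all
#'   set members (supply the expression-matrix genes for a pipeline run).
#' @param alternative passed to [hyper_enrichment_p()]; one-sided
#'   enrichment by default, the ORA convention.
#' @return tibble `term_id`, `term_name`, `k`, `n`, `K`, `N`, `p`,
#'   `fdr`, sorted by `p`.
#' @export
over_representation <- function(query, gene_sets, universe = NULL,
                                alternative = "greater") {
  sets <- as_gene_sets(gene_sets)
  universe <- unique(as.character(universe %||% sets$gene))
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    inform(sprintf("%d query gene(s) outside the universe dropped", length(dropped)))
  }
  query <- intersect(query, universe)
  if (length(query) == 0) abort("empty query after restriction to the universe")
  sets <- sets |> filter(.data$gene %in% universe)
  if (nrow(sets) == 0) abort("no gene sets overlap the universe")
  res <- sets |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(k = sum(.data$gene %in% query),
              K = dplyr::n(), .groups = "drop") |>
    mutate(n = length(query), N = length(universe))
  res$p <- hyper_enrichment_p(res$k, res$n, res$K, res$N,
                              alternative = alternative)
  res |>
    mutate(fdr = p.adjust(.data$p, method = "BH")) |>
    select("term_id", "term_name", "k", "n", "K", "N", "p", "fdr") |>
    arrange(.data$p)
}

#' Jaccard crosstalk edges between enriched terms
#'
#' For every pair of terms significant at `alpha_fdr`, computes the
#' Jaccard index of their gene sets, `|A n B| / |A u B|`, and keeps
#' pairs with `J >= j_min` (boundary inclusive). These are the edges of
#' an enrichment-map-style term network.
#'
#' @param results output of [over_representation()].
#' @param gene_sets same collection used for the enrichment.
#' @param j_min minimum Jaccard index (`>=`).
#' @param alpha_fdr FDR cutoff selecting the terms to connect.
#' @return tibble `term_a`, `term_b`, `jaccard`, sorted by decreasing
#'   `jaccard`.
#' @export
term_jaccard_edges <- function(results, gene_sets, j_min = 0.5,
                               alpha_fdr = 0.05) {
  if (nrow(results) == 0) abort("results is empty")
  sets <- as_gene_sets(gene_sets)
  sig <- results |> filter(.data$fdr < alpha_fdr)
  members <- split(sets$gene, sets$term_id)
  terms <- intersect(sig$term_id, names(members))
  if (length(terms) < 2) {
    return(tibble(term_a = character(), term_b = character(),
                  jaccard = numeric()))
  }
  pairs <- utils::combn(terms, 2)
  jac <- map_dbl(seq_len(ncol(pairs)), function(i) {
    A <- unique(members[[pairs[1, i]]])
    B <- unique(members[[pairs[2, i]]])
    length(intersect(A, B)) / length(union(A, B))
  })
  tibble(term_a = pairs[1, ], term_b = pairs[2, ], jaccard = jac) |>
    filter(.data$jaccard >= j_min) |>
    arrange(desc(.data$jaccard))
}
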