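# The neighbourhood Fisher statistic: for each node, is its direct
# neighbourhood enriched for EI/ES genes relative to the whole network?

#' Per-node neighbourhood Fisher enrichment
#'
#' For a focal gene with `m` neighbours of which `a` are EI/ES, against a
#' network of `N` genes containing `K` EI/ES genes, the statistic is
#' Fisher's exact test on the 2x2 table
#' `[[a, m - a], [K - a, N - m - K + a]]`. The focal gene is excluded
#' from its own neighbourhood (no self-loops) and from `K` when it is
#' itself EI/ES. Degree-0 nodes get `fisher_p = 1` with `a = 0`.
#'
#' The default is the two-sided exact test; `alternative = "greater"`
#' gives the pure enrichment tail `P(X >= a)`. EI/ES genes absent from
#' the network are dropped with a warning and do not count towards `K`.
#'
#' @param net a [ppi_network()] (typically the full background PPI).
#' @param eies_genes character vector of EI/ES gene symbols.
#' @param genes nodes to test; default all nodes with degree >= 1. Pass
#'   e.g. the EI/ES genes themselves to test only the interaction
#'   subnet's members.
#' @param alternative sidedness of the exact test.
#' @return tibble, one row per tested gene: `gene`, `a` (EI/ES
#'   neighbours), `b` (other neighbours), `K`, `N`,
#'   `neighborhood_frac = a / (a + b)`, `fisher_p`; sorted as given.
#' @export
neighborhood_fisher <- function(net, eies_genes, genes = NULL,
                                alternative = c("two.sided", "greater")) {
  stopifnot(inherits(net, "ppi_network"))
  alternative <- match.arg(alternative)
  eies_genes <- unique(as.character(eies_genes))
  absent <- setdiff(eies_genes, net$nodes)
  if (length(absent) > 0) {
    warn(sprintf("%d EI/ES gene(s) not in the network; dropped from K",
                 length(absent)))
  }
  eies <- intersect(eies_genes, net$nodes)
  N <- length(net$nodes)
  deg <- igraph::degree(net$graph)
  if (is.null(genes)) {
    genes <- net$nodes[deg[net$nodes] >= 1]
  } else {
    genes <- as.character(genes)
    missing <- setdiff(genes, net$nodes)
    if (length(missing) > 0) {
      abort(sprintf("gene(s) not in network: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  adj <- igraph::adjacent_vertices(net$graph, genes)
  eies_idx <- which(net$nodes %in% eies)
  a <- unname(map_int(adj, function(nb) sum(as.integer(nb) %in% eies_idx)))
  m <- unname(lengths(adj))
  K <- length(eies) - as.integer(genes %in% eies)
  out <- tibble(
    gene = genes,
    a = a,
    b = as.integer(m - a),
    K = K,
    N = N,
    neighborhood_frac = ifelse(m > 0, a / m, NA_real_),
    fisher_p = 1
  )
  pos <- m > 0
  if (any(pos)) {
    out$fisher_p[pos] <- hyper_enrichment_p(a[pos], m[pos], K[pos], N,
                                            alternative = alternative)
  }
  out
}

#' Call hub genes from neighbourhood enrichment statistics
#'
#' Applies Benjamini-Hochberg FDR across all tested nodes and flags as
#' hubs the genes with `fdr < fdr_max` and at least `min_hits` EI/ES
#' neighbours. Results are sorted by `fisher_p`.
#'
#' @param stats output of [neighborhood_fisher()].
#' @param fdr_max FDR threshold (strict `<`).
#' @param min_hits minimum EI/ES neighbour count (`>=`).
#' @param n_tests number of tests for the BH correction; defaults to
#'   `nrow(stats)`. Supply a larger value when `stats` holds only a
#'   subset of the tested nodes.
#' @return `stats` with `fdr` and `is_hub` columns, sorted by
#'   `fisher_p`; filter on `is_hub` for the hub list.
#' @export
call_hubs <- function(stats, fdr_max = 0.05, min_hits = 5, n_tests = NULL) {
  n_tests <- max(n_tests %||% nrow(stats), nrow(stats))
  stats |>
    mutate(
      fdr = p.adjust(.data$fisher_p, method = "BH", n = n_tests),
      is_hub = .data$fdr < fdr_max & .data$a >= min_hits
    ) |>
    arrange(.data$fisher_p)
}
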