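# PPI network container and plumbing: reading HIPPIE-style edge lists,
# induced subnetworks, degree distributions. The graph machinery is
# igraph; methylhub adds the analysis-specific surface.

#' Build a PPI network from an edge table
#'
#' Edges are undirected; duplicates (in either orientation) and
#' self-loops are dropped, self-loop removals with a message.
#'
#' @param edges data frame whose first two columns are gene symbols;
#'   extra columns are ignored.
#' @param nodes optional vector of node names to include even when they
#'   carry no edge (isolated proteins stay part of the background `N`).
#' @return a `ppi_network`: list with the `igraph` graph and the node
#'   vector.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    abort("edges must be a data frame with >= 2 columns")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (length(a) == 0) abort("empty network")
  loops <- a == b
  if (any(loops)) inform(sprintf("dropped %d self-loop(s)", sum(loops)))
  a2 <- pmin(a[!loops], b[!loops])
  b2 <- pmax(a[!loops], b[!loops])
  keep <- !duplicated(paste0(a2, "\r", b2))
  if (!any(keep)) abort("empty network")
  vertices <- union(union(a2[keep], b2[keep]), as.character(nodes %||% character(0)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a2[keep], to = b2[keep]), directed = FALSE,
    vertices = vertices)
  structure(list(graph = g, nodes = igraph::V(g)$name),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges, mean degree %.2f\n",
              length(x$nodes), igraph::ecount(x$graph),
              2 * igraph::ecount(x$graph) / max(1, length(x$nodes))))
  invisible(x)
}

#' Read a HIPPIE-style PPI edge list
#'
#' Tab- or whitespace-separated text, one interaction per line, first
#' two fields the interacting gene symbols; further fields (scores,
#' evidence) are ignored. Malformed lines raise an error naming the line
#' number.
#'
#' @param path file path.
#' @param header does the first line carry column names?
#' @return a [ppi_network()].
#' @export
read_ppi <- function(path, header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty network")
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    abort(sprintf("malformed edge line %d: need two gene columns",
                  which(nf < 2)[1] + as.integer(header)))
  }
  ppi_network(tibble(from = map_chr(fields, 1), to = map_chr(fields, 2)))
}

#' Induced EI/ES subnetwork with mapping report
#'
#' Intersects a gene set with the network nodes and induces the
#' subgraph; the report counts genes mapped into the network, genes with
#' at least one interaction within the subnet, and the mean neighbour
#' count within the subnet (over mapped genes).
#'
#' @param net a [ppi_network()].
#' @param genes character vector of gene symbols (e.g. EI/ES calls).
#' @return list with `subnet` (a `ppi_network`, possibly empty) and
#'   `report` (tibble `n_input`, `n_mapped`, `n_with_interactions`,
#'   `mean_degree`).
#' @export
extract_subnet <- function(net, genes) {
  stopifnot(inherits(net, "ppi_network"))
  genes <- unique(as.character(genes))
  mapped <- intersect(genes, net$nodes)
  sub <- igraph::induced_subgraph(net$graph, mapped)
  deg <- igraph::degree(sub)
  report <- tibble(
    n_input = length(genes),
    n_mapped = length(mapped),
    n_with_interactions = sum(deg >= 1),
    mean_degree = if (length(mapped) > 0) mean(deg) else NA_real_
  )
  subnet <- structure(list(graph = sub, nodes = igraph::V(sub)$name),
                      class = "ppi_network")
  list(subnet = subnet, report = report)
}

#' Degree distribution of a network
#'
#' Exact histogram of node degrees (isolates included as degree 0), with
#' a heavy-tail summary: the fraction of adjacent occupied degree bins
#' whose node count decreases as degree increases. The check is
#' reported, never enforced.
#'
#' @param net a [ppi_network()].
#' @return tibble `degree`, `n_nodes`, carrying attributes
#'   `tail_decreasing_frac` and `mean_degree`.
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  deg <- igraph::degree(net$graph)
  tab <- tibble(degree = as.integer(names(table(deg))),
                n_nodes = as.integer(table(deg))) |>
    arrange(.data$degree)
  frac <- if (nrow(tab) > 1) mean(diff(tab$n_nodes) < 0) else NA_real_
  attr(tab, "tail_decreasing_frac") <- frac
  attr(tab, "mean_degree") <- mean(deg)
  tab
}
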