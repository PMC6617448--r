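# ggplot2 views of the main result tables. Each takes the tibble a
# pipeline stage returns and gives back a ggplot the caller can theme.

#' Plot the DMP-count distribution
#'
#' Bar chart of genes by number of direction-consistent promoter DMPs.
#'
#' @param dmgs output of [consolidate_dmgs()].
#' @return a ggplot.
#' @export
plot_dmp_distribution <- function(dmgs) {
  dist <- dmp_count_distribution(dmgs)
  ggplot2::ggplot(dist, ggplot2::aes(factor(.data$n_dmps), .data$n_genes)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "significant promoter DMPs per gene",
                  y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot a network degree distribution
#'
#' Node count against degree on log-log axes; a roughly linear decay is
#' the scale-free signature.
#'
#' @param net a [ppi_network()] or a [degree_distribution()] table.
#' @return a ggplot.
#' @export
plot_degree_distribution <- function(net) {
  dist <- if (inherits(net, "ppi_network")) degree_distribution(net) else net
  ggplot2::ggplot(dist |> filter(.data$degree > 0),
                  ggplot2::aes(.data$degree, .data$n_nodes)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "nodes") +
    ggplot2::theme_minimal()
}

#' Plot neighbourhood enrichment statistics
#'
#' EI/ES neighbour count against -log10 Fisher p per node, hubs
#' highlighted.
#'
#' @param hubs output of [call_hubs()].
#' @return a ggplot.
#' @export
plot_hub_stats <- function(hubs) {
  ggplot2::ggplot(hubs, ggplot2::aes(.data$a, -log10(.data$fisher_p),
                                     colour = .data$is_hub)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "EI/ES genes among neighbours",
                  y = expression(-log[10] ~ "Fisher p"),
                  colour = "hub") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential calls
#'
#' Effect size against -log10 p for DEG or DMP tables.
#'
#' @param diff output of [call_degs()] or [call_dmps()].
#' @return a ggplot.
#' @export
plot_volcano <- function(diff) {
  effect <- if ("log2fc" %in% names(diff)) "log2fc" else "delta_beta"
  ggplot2::ggplot(diff, ggplot2::aes(.data[[effect]], -log10(.data$p_value),
                                     colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = effect, y = expression(-log[10] ~ p),
                  colour = "significant") +
    ggplot2::theme_minimal()
}
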