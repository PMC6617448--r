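# Simulation configuration: one validated object holds every knob of the
# synthetic cohort, so a config plus a seed pins the whole fixture down.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic paired
#' tumour/normal cohort. The defaults describe the scale of a typical
#' matched 450K/RNA-Seq study: 21 matched pairs, 2000 genes with mostly
#' single-probe promoters, 10 planted epigenetically induced (EI) and 10
#' planted epigenetically suppressed (ES) genes, a scale-free PPI with 4
#' planted hub nodes whose neighbourhoods are half EI/ES.
#'
#' @param n_pairs matched tumour/normal pairs.
#' @param n_genes total genes.
#' @param probes_per_promoter_dist probability weights over 1..10 probes
#'   per promoter (normalised internally).
#' @param n_ei_planted,n_es_planted planted EI/ES gene counts.
#' @param beta_shift magnitude of the planted tumour-normal beta
#'   difference (EI genes get `-|beta_shift|`, ES genes `+|beta_shift|`).
#' @param expr_log2fc magnitude of the planted expression log2 fold
#'   change (EI up, ES down in tumour).
#' @param noise_sd_beta per-sample methylation noise SD on the M-value
#'   (base-2 logit) scale.
#' @param noise_sd_expr per-sample expression noise SD on the log2
#'   scale.
#' @param coupling_frac fraction of the planted genes' noise variance
#'   carried by a shared per-sample latent factor that raises
#'   methylation while lowering expression, creating the negative
#'   methylation-expression correlation the EI/ES filter screens for.
#' @param na_frac fraction of beta entries masked missing (exercises the
#'   missing-value filter and kNN imputation).
#' @param cross_reactive_frac,snp_frac fractions of probes flagged
#'   cross-reactive / SNP-overlapping.
#' @param ppi_n_nodes,ppi_attach_m preferential-attachment network size
#'   and edges added per node (`ppi_n_nodes >= n_genes`,
#'   `ppi_attach_m < ppi_n_nodes`).
#' @param n_hubs_planted planted hub nodes.
#' @param hub_ei_frac fraction of a planted hub's neighbours drawn from
#'   the planted EI/ES genes.
#' @param hub_degree neighbourhood size given to each planted hub.
#' @param censor_rate probability that a survival record is censored.
#' @param hazard_ratio multiplicative hazard of the high-expression
#'   group relative to low.
#' @param seed integer seed; identical configs give bit-identical
#'   output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 21,
                       n_genes = 2000,
                       probes_per_promoter_dist = 0.5^(1:10),
                       n_ei_planted = 10,
                       n_es_planted = 10,
                       beta_shift = 0.3,
                       expr_log2fc = 2,
                       noise_sd_beta = 0.5,
                       noise_sd_expr = 0.5,
                       coupling_frac = 0.5,
                       na_frac = 0.02,
                       cross_reactive_frac = 0.01,
                       snp_frac = 0.01,
                       ppi_n_nodes = 2000,
                       ppi_attach_m = 5,
                       n_hubs_planted = 4,
                       hub_ei_frac = 0.5,
                       hub_degree = 16,
                       censor_rate = 0.2,
                       hazard_ratio = 3,
                       seed = 1L) {
  cfg <- list(
    n_pairs = n_pairs, n_genes = n_genes,
    probes_per_promoter_dist = probes_per_promoter_dist,
    n_ei_planted = n_ei_planted, n_es_planted = n_es_planted,
    beta_shift = beta_shift, expr_log2fc = expr_log2fc,
    noise_sd_beta = noise_sd_beta, noise_sd_expr = noise_sd_expr,
    coupling_frac = coupling_frac, na_frac = na_frac,
    cross_reactive_frac = cross_reactive_frac, snp_frac = snp_frac,
    ppi_n_nodes = ppi_n_nodes, ppi_attach_m = ppi_attach_m,
    n_hubs_planted = n_hubs_planted, hub_ei_frac = hub_ei_frac,
    hub_degree = hub_degree,
    censor_rate = censor_rate, hazard_ratio = hazard_ratio,
    seed = as.integer(seed)
  )
  check_field <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(sprintf("invalid sim_config field '%s': %s", field, msg))
  }
  check_field(n_pairs >= 2, "n_pairs", "need >= 2 pairs")
  check_field(n_genes >= 1, "n_genes", "need >= 1 gene")
  check_field(length(probes_per_promoter_dist) == 10 &&
                all(probes_per_promoter_dist >= 0) &&
                sum(probes_per_promoter_dist) > 0,
              "probes_per_promoter_dist",
              "need 10 non-negative weights with positive sum")
  check_field(n_ei_planted >= 0 && n_es_planted >= 0 &&
                n_ei_planted + n_es_planted <= n_genes,
              "n_ei_planted", "n_ei_planted + n_es_planted must be <= n_genes")
  check_field(abs(beta_shift) <= 1, "beta_shift", "must lie in [-1, 1]")
  check_field(noise_sd_beta >= 0, "noise_sd_beta", "must be >= 0")
  check_field(noise_sd_expr >= 0, "noise_sd_expr", "must be >= 0")
  check_field(coupling_frac >= 0 && coupling_frac <= 1, "coupling_frac",
              "must lie in [0, 1]")
  check_field(na_frac >= 0 && na_frac < 1, "na_frac", "must lie in [0, 1)")
  check_field(cross_reactive_frac >= 0 && cross_reactive_frac < 1,
              "cross_reactive_frac", "must lie in [0, 1)")
  check_field(snp_frac >= 0 && snp_frac < 1, "snp_frac", "must lie in [0, 1)")
  check_field(ppi_n_nodes >= n_genes, "ppi_n_nodes", "must be >= n_genes")
  check_field(ppi_attach_m >= 1 && ppi_attach_m < ppi_n_nodes,
              "ppi_attach_m", "must satisfy 1 <= m < ppi_n_nodes")
  check_field(n_hubs_planted >= 0, "n_hubs_planted", "must be >= 0")
  check_field(hub_ei_frac >= 0 && hub_ei_frac <= 1, "hub_ei_frac",
              "must lie in [0, 1]")
  check_field(hub_degree >= 1, "hub_degree", "must be >= 1")
  check_field(censor_rate >= 0 && censor_rate <= 1, "censor_rate",
              "must lie in [0, 1]")
  check_field(hazard_ratio > 0, "hazard_ratio", "must be > 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d pairs, %d genes (%d EI + %d ES planted), ",
    "beta_shift %.2g, log2fc %.2g\n  PPI %d nodes (m = %d), %d hubs planted, ",
    "hub_ei_frac %.2g; seed %d\n"),
    x$n_pairs, x$n_genes, x$n_ei_planted, x$n_es_planted,
    x$beta_shift, x$expr_log2fc, x$ppi_n_nodes, x$ppi_attach_m,
    x$n_hubs_planted, x$hub_ei_frac, x$seed))
  invisible(x)
}

# Offset the user seed into distinct, reproducible streams for the three
# generators while staying inside 32-bit integer range.
sim_seed <- function(config, stream) {
  as.integer((abs(config$seed) + 97L * stream) %% .Machine$integer.max)
}
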