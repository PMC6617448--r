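# Fixture builders shared across test files. Everything is constructed
# in code; no data files.

# pairing table for n matched tumour/normal pairs with T../N.. ids
make_pairing <- function(n) {
  tibble::tibble(
    sample_id = c(sprintf("T%02d", seq_len(n)), sprintf("N%02d", seq_len(n))),
    pair_id = rep(sprintf("P%02d", seq_len(n)), 2),
    group = rep(c("tumor", "normal"), each = n)
  )
}

# wrap a named matrix as the (id, samples...) tibble the package consumes
as_feature_tbl <- function(m, id_col = "feature_id") {
  tibble::as_tibble(m) |>
    dplyr::mutate("{id_col}" := rownames(m), .before = 1)
}

# minimal probe annotation; defaults put every probe inside its gene's
# promoter window on the + strand
make_annotation <- function(probe_id, gene = probe_id,
                            chrom = "chr1", pos = 10000, strand = "+",
                            tss = 10000, cross_reactive = FALSE,
                            snp_flag = FALSE) {
  tibble::tibble(probe_id = probe_id, chrom = chrom, pos = pos,
                 strand = strand, gene = gene, tss = tss,
                 cross_reactive = cross_reactive, snp_flag = snp_flag)
}

# a small high-power simulated cohort used by several integration-level
# tests (fast: few hundred genes)
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(n_genes = 300, n_pairs = 12, n_ei_planted = 5,
                   n_es_planted = 5, ppi_n_nodes = 300, ppi_attach_m = 3,
                   n_hubs_planted = 2, hub_degree = 12, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
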