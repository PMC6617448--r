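# Synthetic paired cohort generator: probe annotation, beta and
# expression matrices with planted EI/ES genes, a scale-free PPI with
# planted hubs, survival times with a group-specific hazard, and small
# gene-set collections. All outputs are labelled synthetic stand-ins for
# the cohort-scale inputs the analysis normally consumes.

#' Simulate a paired methylation/expression cohort
#'
#' Generates a probe annotation (autosomal genes, strand-aware TSS,
#' 1-10 promoter probes each), a beta matrix and an expression matrix
#' over matched tumour/normal pairs, plus a truth table of the planted
#' labels.
#'
#' Methylation is generated on the M-value (base-2 logit) scale and
#' transformed back, so betas land in (0, 1) without clipping. Planted
#' EI genes have tumour promoter betas lower by about `beta_shift` and
#' tumour expression higher by `expr_log2fc` log2 units; planted ES
#' genes the converse; null genes have no systematic shift. Within
#' planted genes, a shared per-sample latent factor moves methylation
#' and expression in opposite directions (fraction `coupling_frac` of
#' the noise variance), so their negative correlation holds per sample,
#' not only between groups.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (tibble `probe_id`, `chrom`, `pos`,
#'   `strand`, `gene`, `tss`, `cross_reactive`, `snp_flag`), `beta`
#'   (tibble, probes x samples, `na_frac` entries missing), `expr`
#'   (tibble, genes x samples, FPKM-like), `pairing` (tibble
#'   `sample_id`, `pair_id`, `group`) and `truth` (tibble `gene`,
#'   `label` in `"EI"`/`"ES"`/`"null"`).
#' @export
simulate_methylation_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sim_seed(config, 1L), {
    n_g <- config$n_genes
    n_p <- config$n_pairs
    genes <- sprintf("g%04d", seq_len(n_g))
    label <- rep("null", n_g)
    planted <- sample.int(n_g, config$n_ei_planted + config$n_es_planted)
    label[planted[seq_len(config$n_ei_planted)]] <- "EI"
    label[planted[-seq_len(config$n_ei_planted)]] <- "ES"
    truth <- tibble(gene = genes, label = label)

    pairing <- tibble(
      sample_id = c(sprintf("T%02d", seq_len(n_p)), sprintf("N%02d", seq_len(n_p))),
      pair_id = rep(sprintf("P%02d", seq_len(n_p)), 2),
      group = rep(c("tumor", "normal"), each = n_p)
    )
    samples <- pairing$sample_id
    is_tumor <- pairing$group == "tumor"

    # annotation: autosomal placement, strand-aware promoter probes
    n_probes_per <- sample(1:10, n_g, replace = TRUE,
                           prob = config$probes_per_promoter_dist /
                             sum(config$probes_per_promoter_dist))
    gene_idx <- rep(seq_len(n_g), n_probes_per)
    n_probes <- length(gene_idx)
    chrom <- paste0("chr", sample(1:22, n_g, replace = TRUE))
    strand <- sample(c("+", "-"), n_g, replace = TRUE)
    tss <- sample.int(1e8, n_g) + 1e4
    offset <- sample(-1500:500, n_probes, replace = TRUE)
    pos <- ifelse(strand[gene_idx] == "+",
                  tss[gene_idx] + offset, tss[gene_idx] - offset)
    annotation <- tibble(
      probe_id = sprintf("cg%06d", seq_len(n_probes)),
      chrom = chrom[gene_idx],
      pos = pos,
      strand = strand[gene_idx],
      gene = genes[gene_idx],
      tss = tss[gene_idx],
      cross_reactive = runif(n_probes) < config$cross_reactive_frac,
      snp_flag = runif(n_probes) < config$snp_frac
    )

    # group-level mean betas per probe; planted genes shifted in tumour
    shift <- abs(config$beta_shift)
    gene_label <- label[gene_idx]
    base_normal <- runif(n_probes, 0.1, 0.9)
    base_normal[gene_label == "EI"] <- runif(sum(gene_label == "EI"),
                                             min(0.05 + shift, 0.9), 0.95)
    base_normal[gene_label == "ES"] <- runif(sum(gene_label == "ES"),
                                             0.05, max(0.95 - shift, 0.1))
    base_tumor <- base_normal +
      ifelse(gene_label == "EI", -shift, ifelse(gene_label == "ES", shift, 0))
    base_tumor <- pmin(pmax(base_tumor, 0.02), 0.98)

    # shared latent factor couples planted methylation and expression
    z <- matrix(0, n_g, 2 * n_p)
    z[planted, ] <- rnorm(length(planted) * 2 * n_p)
    sd_b <- config$noise_sd_beta
    sd_shared_b <- sqrt(config$coupling_frac) * sd_b
    sd_indep_b <- sqrt(1 - config$coupling_frac) * sd_b

    m_mean <- matrix(beta_to_m(base_normal), n_probes, 2 * n_p)
    m_mean[, is_tumor] <- beta_to_m(base_tumor)
    # null rows carry the full noise SD independently so marginal
    # variance matches the planted rows (whose variance is split with
    # the shared factor)
    row_sd_b <- ifelse(gene_label == "null", sd_b, sd_indep_b)
    noise_b <- matrix(rnorm(n_probes * 2 * n_p), n_probes, 2 * n_p) * row_sd_b
    shared_b <- sd_shared_b * z[gene_idx, , drop = FALSE]
    beta_m <- m_to_beta(m_mean + shared_b + noise_b)
    dimnames(beta_m) <- list(annotation$probe_id, samples)

    # expression: log2-normal baseline, planted fold change in tumour
    lfc <- abs(config$expr_log2fc)
    base_log2 <- rnorm(n_g, mean = 6, sd = 1.5)
    e_mean <- matrix(base_log2, n_g, 2 * n_p)
    e_mean[label == "EI", is_tumor] <- e_mean[label == "EI", is_tumor] + lfc
    e_mean[label == "ES", is_tumor] <- e_mean[label == "ES", is_tumor] - lfc
    sd_e <- config$noise_sd_expr
    sd_shared_e <- sqrt(config$coupling_frac) * sd_e
    sd_indep_e <- sqrt(1 - config$coupling_frac) * sd_e
    row_sd_e <- ifelse(label == "null", sd_e, sd_indep_e)
    noise_e <- matrix(rnorm(n_g * 2 * n_p), n_g, 2 * n_p) * row_sd_e
    expr_m <- 2^(e_mean - sd_shared_e * z + noise_e)
    dimnames(expr_m) <- list(genes, samples)

    if (config$na_frac > 0) {
      mask <- matrix(runif(length(beta_m)) < config$na_frac,
                     nrow(beta_m), ncol(beta_m))
      beta_m[mask] <- NA_real_
    }

    list(
      annotation = annotation,
      beta = matrix_to_tbl(beta_m, "probe_id"),
      expr = matrix_to_tbl(expr_m, "gene"),
      pairing = pairing,
      truth = truth
    )
  })
}

#' Simulate a scale-free PPI with planted hubs
#'
#' A preferential-attachment (Barabasi-Albert) background graph over
#' `ppi_n_nodes` nodes, the first `n_genes` of which carry the simulated
#' gene symbols (assigned in random order so planted genes do not
#' inherit systematically old, high-degree positions). Each planted hub
#' is a non-planted gene whose incident edges are then rewired to a
#' neighbourhood of size `hub_degree` containing
#' `ceiling(hub_ei_frac * hub_degree)` planted EI/ES genes.
#'
#' @param config a [sim_config()].
#' @param truth truth tibble from [simulate_methylation_expression()].
#' @return list with `edges` (tibble `from`, `to`) and `planted_hubs`
#'   (character vector).
#' @export
simulate_ppi <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  planted <- truth$gene[truth$label != "null"]
  n_need <- ceiling(config$hub_ei_frac * config$hub_degree)
  if (config$n_hubs_planted > 0 && n_need > length(planted)) {
    abort(sprintf(
      "invalid sim_config field 'hub_ei_frac': hubs need %d planted neighbours but only %d genes are planted",
      n_need, length(planted)))
  }
  withr::with_seed(sim_seed(config, 2L), {
    g <- igraph::sample_pa(config$ppi_n_nodes, m = config$ppi_attach_m,
                           directed = FALSE)
    nodes <- character(config$ppi_n_nodes)
    gene_slots <- sample.int(config$ppi_n_nodes, config$n_genes)
    nodes[gene_slots] <- sample(truth$gene)
    extra <- setdiff(seq_len(config$ppi_n_nodes), gene_slots)
    nodes[extra] <- sprintf("ext%05d", seq_along(extra))
    igraph::V(g)$name <- nodes

    candidates <- setdiff(truth$gene[truth$label == "null"], character(0))
    hubs <- if (config$n_hubs_planted > 0) {
      sample(candidates, config$n_hubs_planted)
    } else character(0)
    non_planted_pool <- setdiff(nodes, c(planted, hubs))
    for (h in hubs) {
      old <- igraph::incident(g, h)
      g <- igraph::delete_edges(g, old)
      nb_planted <- sample(planted, n_need)
      nb_other <- sample(non_planted_pool, config$hub_degree - n_need)
      g <- igraph::add_edges(g, rbind(h, c(nb_planted, nb_other)))
    }
    g <- igraph::simplify(g)
    e <- igraph::as_data_frame(g, what = "edges")
    list(edges = as_tibble(e), planted_hubs = hubs)
  })
}

#' Simulate survival times with a group-specific hazard
#'
#' Event times are exponential with hazard `log(2)/36` per month for the
#' low group and `hazard_ratio` times that for the high group (median
#' survival 36 months in the low group). Censoring is an independent
#' exponential time calibrated so each record is censored with
#' probability `censor_rate`; `censor_rate = 1` censors everything.
#'
#' @param groups tibble with `sample_id` and `group`
#'   (`"high"`/`"low"`), e.g. from [split_by_expression()].
#' @param config a [sim_config()].
#' @return tibble `sample_id`, `time` (months), `event` (1 = event,
#'   0 = censored), `group`.
#' @export
simulate_survival <- function(groups, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("groups needs columns sample_id and group")
  }
  if (!all(groups$group %in% c("high", "low"))) {
    abort("group must be 'high' or 'low'")
  }
  withr::with_seed(sim_seed(config, 3L), {
    base_rate <- log(2) / 36
    rate <- ifelse(groups$group == "high",
                   base_rate * config$hazard_ratio, base_rate)
    t_event <- rexp(nrow(groups), rate)
    cr <- config$censor_rate
    if (cr >= 1) {
      time <- t_event
      event <- rep(0L, nrow(groups))
    } else if (cr == 0) {
      time <- t_event
      event <- rep(1L, nrow(groups))
    } else {
      c_rate <- rate * cr / (1 - cr)
      t_cens <- rexp(nrow(groups), c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    tibble(sample_id = groups$sample_id, time = time, event = event,
           group = groups$group)
  })
}

#' Simulate a small gene-set collection
#'
#' Random gene sets over the simulated gene universe plus one set spiked
#' with the planted EI genes and one with the planted ES genes, so the
#' over-representation stage has signal to find. Synthetic stand-in for
#' user-supplied GMT collections.
#'
#' @param config a [sim_config()].
#' @param truth truth tibble from [simulate_methylation_expression()].
#' @param n_sets number of random background sets.
#' @param set_size_range set sizes drawn uniformly from this range.
#' @return long tibble `term_id`, `term_name`, `gene`.
#' @export
simulate_gene_sets <- function(config, truth, n_sets = 50,
                               set_size_range = c(10, 100)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sim_seed(config, 4L), {
    sizes <- sample(set_size_range[1]:set_size_range[2], n_sets, replace = TRUE)
    rand <- dplyr::bind_rows(map(seq_len(n_sets), function(i) {
      tibble(term_id = sprintf("SET%03d", i),
             term_name = sprintf("random set %d", i),
             gene = sample(truth$gene, min(sizes[i], nrow(truth))))
    }))
    spike <- function(lbl, id, nm) {
      members <- truth$gene[truth$label == lbl]
      if (length(members) == 0) return(NULL)
      filler <- sample(truth$gene[truth$label == "null"],
                       min(20, sum(truth$label == "null")))
      tibble(term_id = id, term_name = nm,
             gene = unique(c(members, filler)))
    }
    dplyr::bind_rows(rand, spike("EI", "SET_EI", "planted EI pathway"),
                     spike("ES", "SET_ES", "planted ES pathway"))
  })
}

#' Write a simulated cohort to tab-separated files
#'
#' Writes annotation, beta, expression, pairing, truth, PPI edges and
#' (when supplied) survival and gene sets as plain TSV files.
#'
#' @param sim output of [simulate_methylation_expression()], optionally
#'   augmented with `ppi`, `survival`, `gene_sets` elements.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    annotation = "annotation.tsv", beta = "beta.tsv", expr = "expr.tsv",
    pairing = "pairing.tsv", truth = "truth.tsv"
  )
  for (nm in names(files)) {
    readr::write_tsv(sim[[nm]], file.path(dir, files[[nm]]))
  }
  if (!is.null(sim$ppi)) {
    readr::write_tsv(sim$ppi$edges, file.path(dir, "ppi_edges.tsv"),
                     col_names = FALSE)
    writeLines(sim$ppi$planted_hubs, file.path(dir, "planted_hubs.txt"))
    files <- c(files, ppi = "ppi_edges.tsv", hubs = "planted_hubs.txt")
  }
  if (!is.null(sim$survival)) {
    readr::write_tsv(sim$survival, file.path(dir, "survival.tsv"))
    files <- c(files, survival = "survival.tsv")
  }
  if (!is.null(sim$gene_sets)) {
    readr::write_tsv(sim$gene_sets, file.path(dir, "gene_sets.tsv"))
    files <- c(files, gene_sets = "gene_sets.tsv")
  }
  invisible(setNames(file.path(dir, files), names(files)))
}
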