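# End-to-end orchestration: one validated config carries every input and
# threshold; run_pipeline() sequences the stages and optionally writes
# each stage's table plus a manifest.

#' Pipeline configuration
#'
#' Collects inputs (in-memory tibbles or TSV paths) and every threshold
#' of the integrated analysis. Defaults are the analysis' standard
#' values: p < 0.05 with |log2FC| > 1 for DEGs, p < 0.05 for DMPs, a
#' TSS -1500/+500 bp promoter window, Spearman correlation at p < 0.05,
#' and hub calling at FDR < 0.05 with >= 5 EI/ES neighbours.
#'
#' @param beta,expr,annotation,ppi required inputs: tibbles as produced
#'   by [simulate_methylation_expression()] / [simulate_ppi()], or paths
#'   to TSV files with the same columns (`ppi` may be a path read via
#'   [read_ppi()]).
#' @param pairing pairing tibble or TSV path.
#' @param survival optional survival tibble/path (`sample_id`, `time`,
#'   `event`); when present the top hub gene's tumour expression defines
#'   the high/low split unless a `group` column is already supplied.
#' @param gene_sets optional gene-set tibble/GMT path for the
#'   over-representation stage.
#' @param alpha_deg,lfc_min DEG thresholds.
#' @param alpha_dmp DMP threshold.
#' @param alpha_corr correlation-filter threshold.
#' @param fdr_max,min_hits hub thresholds.
#' @param na_frac_max,k_knn probe-filter and imputation settings.
#' @param upstream,downstream promoter window in bp.
#' @param j_min Jaccard threshold for term-crosstalk edges.
#' @param label_set which confirmed genes feed the hub statistic:
#'   the EI/ES union (default), EI only, or ES only.
#' @param normalize_expr `"tpm"` applies [fpkm_to_tpm()]; `"none"`
#'   passes expression through (inputs already normalised).
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(beta, expr, annotation, ppi, pairing,
                            survival = NULL, gene_sets = NULL,
                            alpha_deg = 0.05, lfc_min = 1.0,
                            alpha_dmp = 0.05, alpha_corr = 0.05,
                            fdr_max = 0.05, min_hits = 5,
                            na_frac_max = 0.70, k_knn = 10,
                            upstream = 1500, downstream = 500,
                            j_min = 0.5,
                            label_set = c("both", "ei", "es"),
                            normalize_expr = c("tpm", "none"),
                            seed = 1L) {
  label_set <- match.arg(label_set)
  normalize_expr <- match.arg(normalize_expr)
  for (nm in c("alpha_deg", "alpha_dmp", "alpha_corr", "fdr_max",
               "na_frac_max", "j_min")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("threshold '%s' must lie in [0, 1]", nm))
    }
  }
  stopifnot(lfc_min >= 0, min_hits >= 0, k_knn >= 1,
            upstream >= 0, downstream >= 0)
  for (nm in c("beta", "expr", "annotation", "ppi", "pairing",
               "survival", "gene_sets")) {
    v <- get(nm)
    if (is.character(v) && length(v) == 1 && !file.exists(v)) {
      abort(sprintf("input '%s': file not found: %s", nm, v))
    }
  }
  structure(list(
    beta = beta, expr = expr, annotation = annotation, ppi = ppi,
    pairing = pairing, survival = survival, gene_sets = gene_sets,
    thresholds = list(
      alpha_deg = alpha_deg, lfc_min = lfc_min, alpha_dmp = alpha_dmp,
      alpha_corr = alpha_corr, fdr_max = fdr_max, min_hits = min_hits,
      na_frac_max = na_frac_max, k_knn = k_knn, upstream = upstream,
      downstream = downstream, j_min = j_min, label_set = label_set,
      normalize_expr = normalize_expr
    ),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

load_input <- function(x, reader = readr::read_tsv) {
  if (is.character(x) && length(x) == 1) {
    return(reader(x, show_col_types = FALSE, progress = FALSE))
  }
  x
}

#' Run the integrated methylation/expression pipeline
#'
#' Sequences the stages: promoter assignment, probe filtering and kNN
#' imputation, expression normalisation, DEG/DMP calling, DMG
#' consolidation, EI/ES candidate pairing and correlation filtering, the
#' neighbourhood Fisher hub statistic over the background PPI, optional
#' gene-set over-representation with Jaccard crosstalk edges, and
#' optional Kaplan-Meier/log-rank survival comparison for the top hub
#' gene. A stage failure aborts with the stage named.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, every stage table is
#'   written as TSV together with `manifest.yaml` (package version,
#'   thresholds, config hash, seed). Rerunning with an identical config
#'   reproduces identical files.
#' @return list with `degs`, `dmps`, `dmgs`, `candidates`, `eies`,
#'   `summary`, `subnet_report`, `hub_stats`, `hubs`, `enrichment`,
#'   `jaccard_edges`, `survival` (list `groups`, `km`, `logrank`, `gene`
#'   or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  annotation <- load_input(config$annotation)
  beta <- load_input(config$beta)
  expr <- load_input(config$expr)
  pairing <- load_input(config$pairing)
  net <- stage("ppi", {
    if (is.character(config$ppi)) read_ppi(config$ppi)
    else if (inherits(config$ppi, "ppi_network")) config$ppi
    else ppi_network(config$ppi)
  })

  assignments <- stage("promoter_assignment",
                       assign_promoter_probes(annotation, th$upstream, th$downstream))
  beta_f <- stage("probe_filter",
                  filter_probes(beta, annotation, na_frac_max = th$na_frac_max))
  beta_f <- stage("imputation", impute_knn(beta_f, k = th$k_knn))
  beta_prom <- beta_f |> filter(.data[[names(beta_f)[1]]] %in% assignments$probe_id)
  if (nrow(beta_prom) == 0) abort("pipeline stage 'promoter_assignment' failed: no promoter probes left")

  expr_n <- if (th$normalize_expr == "tpm") {
    stage("tpm", fpkm_to_tpm(expr))
  } else expr

  degs <- stage("degs", call_degs(expr_n, pairing,
                                  alpha = th$alpha_deg, lfc_min = th$lfc_min))
  dmps <- stage("dmps", call_dmps(beta_prom, pairing, alpha = th$alpha_dmp))
  dmgs <- stage("dmgs", consolidate_dmgs(dmps, assignments))
  candidates <- stage("candidates", pair_candidates(degs, dmgs))
  eies <- stage("correlation_filter",
                correlation_filter(candidates, beta_prom, expr_n,
                                   pairing = pairing, alpha = th$alpha_corr))
  summary <- summarize_ei_es(eies, dmgs)

  confirmed <- eies |> filter(.data$category %in% c("EI", "ES"))
  label_genes <- switch(th$label_set,
    both = confirmed$gene,
    ei = confirmed$gene[confirmed$category == "EI"],
    es = confirmed$gene[confirmed$category == "ES"])
  sub <- stage("subnet", extract_subnet(net, label_genes))
  hub_stats <- stage("hub_statistic",
                     suppressWarnings(neighborhood_fisher(net, label_genes)))
  hubs <- call_hubs(hub_stats, fdr_max = th$fdr_max, min_hits = th$min_hits)

  enrichment <- NULL; jaccard_edges <- NULL
  if (!is.null(config$gene_sets) && nrow(confirmed) > 0) {
    gsc <- load_input(config$gene_sets,
                      reader = function(p, ...) if (grepl("\\.gmt$", p)) read_gmt(p)
                               else readr::read_tsv(p, show_col_types = FALSE))
    universe <- as.character(expr_n[[1]])
    enrichment <- stage("enrichment",
                        over_representation(confirmed$gene, gsc, universe = universe))
    jaccard_edges <- stage("jaccard",
                           term_jaccard_edges(enrichment, gsc, j_min = th$j_min))
  }

  surv_out <- NULL
  if (!is.null(config$survival) && any(hubs$is_hub)) {
    surv_tbl <- load_input(config$survival)
    surv_out <- stage("survival", {
      top_gene <- if (nrow(hubs) > 0) hubs$gene[1] else NA_character_
      if (!"group" %in% names(surv_tbl)) {
        if (is.na(top_gene) || !top_gene %in% expr_n[[1]]) {
          abort("no hub gene available to define expression groups")
        }
        tumor_ids <- Reduce(intersect, list(
          pairing$sample_id[pairing$group == "tumor"],
          surv_tbl$sample_id, colnames(expr_n)[-1]))
        if (length(tumor_ids) < 2) abort("too few tumour samples with survival data")
        vals <- feature_matrix(expr_n)[top_gene, tumor_ids]
        grp <- split_by_expression(vals) |>
          select("sample_id", expr_group = "group")
        surv_tbl <- surv_tbl |>
          inner_join(grp, by = "sample_id") |>
          rename(group = "expr_group")
      }
      list(gene = top_gene, groups = surv_tbl,
           km = km_estimate(surv_tbl), logrank = logrank_test(surv_tbl))
    })
  }

  manifest <- list(
    package = "methylhub",
    version = as.character(utils::packageVersion("methylhub")),
    seed = config$seed,
    thresholds = th,
    config_hash = rlang::hash(list(th, config$seed)),
    n_probes_tested = nrow(dmps), n_genes_tested = nrow(degs),
    n_ei = summary$counts$n_ei, n_es = summary$counts$n_es,
    n_hubs = sum(hubs$is_hub)
  )

  out <- list(degs = degs, dmps = dmps, dmgs = dmgs,
              candidates = candidates, eies = eies, summary = summary,
              subnet_report = sub$report, hub_stats = hub_stats,
              hubs = hubs, enrichment = enrichment,
              jaccard_edges = jaccard_edges, survival = surv_out,
              manifest = manifest)
  if (!is.null(outdir)) write_pipeline_results(out, outdir)
  out
}

write_pipeline_results <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) {
    if (is.null(tbl)) return()
    tbl <- tbl |> mutate(dplyr::across(dplyr::where(is.list),
                                       ~ map_chr(.x, paste, collapse = ";")))
    readr::write_tsv(tbl, file.path(outdir, paste0(name, ".tsv")))
  }
  w(res$degs, "degs"); w(res$dmps, "dmps"); w(res$dmgs, "dmgs")
  w(res$eies, "eies_calls"); w(res$hubs, "hub_stats")
  w(res$subnet_report, "subnet_report")
  w(res$enrichment, "enrichment"); w(res$jaccard_edges, "jaccard_edges")
  if (!is.null(res$survival)) {
    w(as_tibble(res$survival$km), "km_curve")
    w(glance(res$survival$logrank), "logrank")
  }
  yaml::write_yaml(res$manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
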