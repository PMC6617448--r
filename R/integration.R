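# EI/ES classification: genes significant in both views with opposite
# directions, then a per-gene negative methylation-expression
# correlation filter.

#' Pair DEG and DMG calls into EI/ES candidates
#'
#' An epigenetically induced (EI) candidate is up in expression and down
#' in promoter methylation; an epigenetically suppressed (ES) candidate
#' is the converse. Same-direction pairs and discordant DMGs are
#' excluded.
#'
#' @param degs output of [call_degs()].
#' @param dmgs output of [consolidate_dmgs()].
#' @return tibble `gene`, `deg_direction`, `dmg_direction`, `category`
#'   (`"EI"`/`"ES"`) and list-column `valid_dmp_ids`.
#' @export
pair_candidates <- function(degs, dmgs) {
  sig_deg <- degs |>
    filter(.data$significant) |>
    select(gene = "feature_id", deg_direction = "direction")
  sig_dmg <- dmgs |>
    filter(.data$direction %in% c("up", "down")) |>
    select("gene", dmg_direction = "direction", "valid_dmp_ids")
  sig_deg |>
    inner_join(sig_dmg, by = "gene") |>
    filter(.data$deg_direction != .data$dmg_direction) |>
    mutate(category = ifelse(.data$deg_direction == "up", "EI", "ES")) |>
    select("gene", "deg_direction", "dmg_direction", "category", "valid_dmp_ids")
}

#' Negative methylation-expression correlation filter
#'
#' For each candidate gene, correlates each valid promoter DMP's beta
#' values with the gene's expression across samples (tumour and normal
#' jointly by default, maximising n at typical paired-cohort sizes;
#' `samples = "tumor"` restricts to tumour columns). A candidate is
#' retained — its category confirmed — iff every valid DMP correlates
#' negatively and the smallest correlation p-value is below `alpha`
#' (two-sided p with the sign requirement `corr < 0`). The DMP with the
#' smallest p is recorded as `valid_dmp_used`. Genes whose beta or
#' expression vector is constant cannot be correlated and are dropped to
#' `"none"` with a message.
#'
#' @param candidates output of [pair_candidates()].
#' @param beta imputed promoter beta tibble (probes x samples).
#' @param expr expression tibble (genes x samples).
#' @param pairing pairing tibble; required only for `samples = "tumor"`.
#' @param method correlation method; Spearman by default (robust to the
#'   beta/TPM scale mismatch).
#' @param alpha significance level for the correlation p-value.
#' @param samples correlate across all samples or tumour samples only.
#' @return tibble `gene`, `category` (`"EI"`/`"ES"`/`"none"`),
#'   `deg_direction`, `dmg_direction`, `corr`, `corr_p`,
#'   `valid_dmp_used`.
#' @export
correlation_filter <- function(candidates, beta, expr, pairing = NULL,
                               method = c("spearman", "pearson"),
                               alpha = 0.05,
                               samples = c("all", "tumor")) {
  method <- match.arg(method)
  samples <- match.arg(samples)
  bm <- feature_matrix(beta, "beta")
  em <- feature_matrix(expr, "expression")
  shared <- intersect(colnames(bm), colnames(em))
  if (samples == "tumor") {
    if (is.null(pairing)) abort("samples = 'tumor' needs the pairing table")
    shared <- intersect(shared, pairing$sample_id[pairing$group == "tumor"])
  }
  if (length(shared) < 3) abort("need >= 3 samples shared between beta and expression")
  bm <- bm[, shared, drop = FALSE]
  em <- em[, shared, drop = FALSE]

  if (nrow(candidates) == 0) {
    return(tibble(gene = character(), category = character(),
                  deg_direction = character(), dmg_direction = character(),
                  corr = numeric(), corr_p = numeric(),
                  valid_dmp_used = character()))
  }

  res <- pmap(
    list(candidates$gene, candidates$category, candidates$deg_direction,
         candidates$dmg_direction, candidates$valid_dmp_ids),
    function(gene, category, deg_dir, dmg_dir, dmp_ids) {
      dmp_ids <- intersect(dmp_ids, rownames(bm))
      e <- if (gene %in% rownames(em)) em[gene, ] else NULL
      if (is.null(e) || length(dmp_ids) == 0) {
        inform(sprintf("gene %s: no overlapping data for correlation; dropped", gene))
        return(tibble(gene = gene, category = "none",
                      deg_direction = deg_dir, dmg_direction = dmg_dir,
                      corr = NA_real_, corr_p = NA_real_,
                      valid_dmp_used = NA_character_))
      }
      if (stats::sd(e) == 0) {
        inform(sprintf("gene %s: constant expression; correlation undefined, dropped", gene))
        return(tibble(gene = gene, category = "none",
                      deg_direction = deg_dir, dmg_direction = dmg_dir,
                      corr = NA_real_, corr_p = NA_real_,
                      valid_dmp_used = NA_character_))
      }
      cors <- map(dmp_ids, function(p) {
        b <- bm[p, ]
        if (stats::sd(b) == 0) return(NULL)
        ct <- suppressWarnings(cor.test(b, e, method = method, exact = FALSE))
        tibble(probe = p, corr = unname(ct$estimate), corr_p = ct$p.value)
      })
      cors <- dplyr::bind_rows(cors)
      if (nrow(cors) == 0) {
        inform(sprintf("gene %s: constant beta at all valid DMPs; dropped", gene))
        return(tibble(gene = gene, category = "none",
                      deg_direction = deg_dir, dmg_direction = dmg_dir,
                      corr = NA_real_, corr_p = NA_real_,
                      valid_dmp_used = NA_character_))
      }
      best <- cors |> arrange(.data$corr_p, .data$probe) |> dplyr::slice(1)
      keep <- all(cors$corr < 0) && best$corr_p < alpha
      tibble(gene = gene,
             category = if (keep) category else "none",
             deg_direction = deg_dir, dmg_direction = dmg_dir,
             corr = best$corr, corr_p = best$corr_p,
             valid_dmp_used = best$probe)
    }
  )
  dplyr::bind_rows(res)
}

#' Summarise EI/ES calls
#'
#' Counts of confirmed EI and ES genes and, when DMG records are
#' supplied, the DMP-count distribution restricted to those genes.
#'
#' @param calls output of [correlation_filter()].
#' @param dmgs optional output of [consolidate_dmgs()] for the
#'   restricted DMP-count distribution.
#' @return list with `counts` (tibble `n_ei`, `n_es`) and
#'   `dmp_distribution` (tibble or `NULL`).
#' @export
summarize_ei_es <- function(calls, dmgs = NULL) {
  counts <- tibble(
    n_ei = sum(calls$category == "EI"),
    n_es = sum(calls$category == "ES")
  )
  dist <- NULL
  if (!is.null(dmgs)) {
    kept <- calls$gene[calls$category %in% c("EI", "ES")]
    dist <- dmp_count_distribution(dmgs |> filter(.data$gene %in% kept))
  }
  list(counts = counts, dmp_distribution = dist)
}
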