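# Paired differential calling: DEGs from expression, DMPs from promoter
# beta values, and consolidation of DMPs into direction-consistent DMGs.

# Row-wise paired t-test. `tum` and `nor` are feature x pair matrices with
# columns aligned by pair. Returns per-feature t, p and a zero-variance
# flag; zero-variance features get p = 1 rather than NaN.
paired_t_rows <- function(tum, nor) {
  d <- tum - nor
  n <- ncol(d)
  if (n < 2) abort("paired t-test needs >= 2 complete pairs")
  mean_d <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - mean_d)^2) / (n - 1))
  zero_var <- sd_d == 0
  t_stat <- ifelse(zero_var, 0, mean_d / (sd_d / sqrt(n)))
  p <- ifelse(zero_var, 1, 2 * pt(-abs(t_stat), df = n - 1))
  if (any(zero_var)) {
    warn(sprintf("%d feature(s) with zero variance of paired differences; p set to 1",
                 sum(zero_var)))
  }
  tibble(t_stat = unname(t_stat), p_value = unname(p),
         zero_variance = unname(zero_var))
}

#' Call differentially expressed genes from paired samples
#'
#' The effect size is the ratio of median tumour to median normal
#' expression over the matched samples, reported as
#' `log2fc = log2((median_tumor + pseudocount) / (median_normal + pseudocount))`.
#' Significance comes from a two-sided paired t-test across pairs,
#' by default on `log2(value + pseudocount)` (fold-change thresholds are
#' stated in log2 units; set `log_scale = FALSE` to test raw values).
#' A gene is significant iff `p < alpha` and `|log2fc| > lfc_min`, both
#' strict.
#'
#' @param expr tibble: first column gene id, then one column per sample
#'   (TPM or comparable non-negative scale).
#' @param pairing tibble with columns `sample_id`, `pair_id`, `group`
#'   (`"tumor"`/`"normal"`); every pair id must map to exactly one tumour
#'   and one normal sample present in `expr`.
#' @param alpha significance level for the paired t-test (strict `<`).
#' @param lfc_min minimum `|log2fc|` (strict `>`).
#' @param log_scale test on `log2(value + pseudocount)` (default) or raw.
#' @param pseudocount added before ratios and logs to stabilise zeros.
#' @return tibble with one row per gene: `feature_id`, `median_tumor`,
#'   `median_normal`, `log2fc`, `p_value`, `direction` (`"up"` iff
#'   `log2fc > 0`), `significant`, `zero_variance`.
#' @export
call_degs <- function(expr, pairing, alpha = 0.05, lfc_min = 1.0,
                      log_scale = TRUE, pseudocount = 1) {
  m <- feature_matrix(expr, "expression")
  sp <- paired_split(m, pairing)
  med_t <- unname(apply(sp$tumor, 1, median))
  med_n <- unname(apply(sp$normal, 1, median))
  log2fc <- log2((med_t + pseudocount) / (med_n + pseudocount))
  tt <- if (log_scale) {
    paired_t_rows(log2(sp$tumor + pseudocount), log2(sp$normal + pseudocount))
  } else {
    paired_t_rows(sp$tumor, sp$normal)
  }
  tibble(
    feature_id = rownames(m),
    median_tumor = med_t,
    median_normal = med_n,
    log2fc = log2fc,
    p_value = tt$p_value,
    direction = ifelse(log2fc > 0, "up", "down"),
    significant = tt$p_value < alpha & abs(log2fc) > lfc_min,
    zero_variance = tt$zero_variance
  )
}

#' Call differentially methylated positions from paired samples
#'
#' Per probe, the effect is `delta_beta = median(tumor) - median(normal)`
#' and the p-value a two-sided paired t-test across pairs, on the beta
#' scale by default (`scale = "mvalue"` tests base-2 logits instead; the
#' reported `delta_beta` stays on the beta scale either way). A position
#' is significant iff `p < alpha`.
#'
#' @param beta tibble: first column probe id, then beta values per sample
#'   (no missing values; impute first).
#' @inheritParams call_degs
#' @param scale scale on which the t-test is run.
#' @return tibble with `feature_id`, `median_tumor`, `median_normal`,
#'   `delta_beta`, `p_value`, `direction` (`"up"` iff `delta_beta > 0`,
#'   i.e. hypermethylated in tumour), `significant`, `zero_variance`.
#' @export
call_dmps <- function(beta, pairing, alpha = 0.05,
                      scale = c("beta", "mvalue")) {
  scale <- match.arg(scale)
  m <- feature_matrix(beta, "beta")
  if (anyNA(m)) abort("beta contains missing values; run impute_knn() first")
  sp <- paired_split(m, pairing)
  med_t <- unname(apply(sp$tumor, 1, median))
  med_n <- unname(apply(sp$normal, 1, median))
  delta <- med_t - med_n
  tt <- if (scale == "beta") {
    paired_t_rows(sp$tumor, sp$normal)
  } else {
    paired_t_rows(beta_to_m(sp$tumor), beta_to_m(sp$normal))
  }
  tibble(
    feature_id = rownames(m),
    median_tumor = med_t,
    median_normal = med_n,
    delta_beta = delta,
    p_value = tt$p_value,
    direction = ifelse(delta > 0, "up", "down"),
    significant = tt$p_value < alpha,
    zero_variance = tt$zero_variance
  )
}

#' Consolidate promoter DMPs into differentially methylated genes
#'
#' A gene's valid DMPs are its significant promoter positions when they
#' all share one direction; genes whose significant positions disagree in
#' sign are marked `"discordant"` and excluded from downstream EI/ES
#' calling. Genes with no significant promoter DMP are omitted.
#'
#' @param dmps output of [call_dmps()].
#' @param assignments promoter assignments from [assign_promoter_probes()].
#' @return tibble with `gene`, `n_dmps`, `direction`
#'   (`"up"`/`"down"`/`"discordant"`) and list-column `valid_dmp_ids`.
#' @export
consolidate_dmgs <- function(dmps, assignments) {
  sig <- dmps |> filter(.data$significant)
  joined <- sig |>
    inner_join(assignments, by = c(feature_id = "probe_id"),
               relationship = "many-to-many")
  joined |>
    group_by(.data$gene) |>
    summarise(
      n_dmps = dplyr::n(),
      direction = if (dplyr::n_distinct(.data$direction) == 1L)
        .data$direction[1] else "discordant",
      valid_dmp_ids = list(.data$feature_id),
      .groups = "drop"
    ) |>
    mutate(valid_dmp_ids = map2(.data$valid_dmp_ids, .data$direction,
                                ~ if (.y == "discordant") character(0) else .x))
}

#' Distribution of DMP counts per gene
#'
#' How many genes carry 1, 2, ... direction-consistent promoter DMPs
#' (discordant genes excluded).
#'
#' @param dmgs output of [consolidate_dmgs()].
#' @return tibble `n_dmps`, `n_genes`; row counts sum to the number of
#'   non-discordant DMGs.
#' @export
dmp_count_distribution <- function(dmgs) {
  dmgs |>
    filter(.data$direction != "discordant") |>
    count(.data$n_dmps, name = "n_genes") |>
    arrange(.data$n_dmps)
}
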