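# Probe filtering, kNN imputation, promoter assignment and FPKM->TPM
# conversion: the steps that turn raw beta/expression tables into
# analysis-ready paired matrices.

#' Filter methylation probes
#'
#' Removes probes flagged as cross-reactive (mapping to multiple genomic
#' locations) or overlapping a SNP, probes on the sex chromosomes, and
#' probes whose missing fraction across samples strictly exceeds
#' `na_frac_max`. Row order of retained probes is preserved.
#'
#' @param beta tibble: first column `probe_id`, remaining columns one
#'   beta value per sample (may contain `NA`).
#' @param annotation probe annotation tibble with columns `probe_id`,
#'   `chrom`, `cross_reactive`, `snp_flag` (see [simulate_methylation_expression()]
#'   for the full schema).
#' @param na_frac_max probes with missing fraction > this are dropped;
#'   the boundary itself is retained ("exceeds" is read strictly).
#' @param sex_chroms chromosome names treated as sex chromosomes.
#' @param na_frac_max_sample optional per-sample missing-fraction cap;
#'   when given, sample columns exceeding it are dropped before the
#'   per-probe filter (off by default; per-probe filtering is the
#'   standard 450K practice).
#' @return the filtered beta tibble.
#' @export
filter_probes <- function(beta, annotation, na_frac_max = 0.70,
                          sex_chroms = c("chrX", "chrY", "X", "Y"),
                          na_frac_max_sample = NULL) {
  stopifnot(is.numeric(na_frac_max), na_frac_max >= 0, na_frac_max <= 1)
  m <- feature_matrix(beta, "beta")
  ann <- annotation[match(rownames(m), annotation$probe_id), ]
  if (anyNA(ann$probe_id)) {
    abort(sprintf("probes missing from annotation: %s",
                  paste(head(setdiff(rownames(m), annotation$probe_id), 5),
                        collapse = ", ")))
  }
  if (!is.null(na_frac_max_sample)) {
    samp_na <- colMeans(is.na(m))
    keep_s <- samp_na <= na_frac_max_sample
    if (!all(keep_s)) {
      inform(sprintf("dropping %d sample(s) with missing fraction > %g",
                     sum(!keep_s), na_frac_max_sample))
    }
    m <- m[, keep_s, drop = FALSE]
  }
  flagged <- ann$cross_reactive | ann$snp_flag
  on_sex <- ann$chrom %in% sex_chroms
  na_frac <- rowMeans(is.na(m))
  keep <- !flagged & !on_sex & na_frac <= na_frac_max
  if (!any(keep)) abort("no probes survive filtering")
  beta[keep, c(names(beta)[1], colnames(m)), drop = FALSE]
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' Each missing entry is replaced by the mean of the `k` nearest probes
#' (rows) that observe that sample, nearness being mean squared
#' difference over the samples both probes observe. Observed entries are
#' returned bit-identical. A probe sharing no observed sample with any
#' other probe falls back to its row mean; a fully missing probe is an
#' error (it should have been removed by [filter_probes()]).
#'
#' @param beta tibble, first column probe id, then sample columns.
#' @param k number of donor neighbours.
#' @return tibble of the same shape with no missing values.
#' @export
impute_knn <- function(beta, k = 10) {
  stopifnot(k >= 1)
  m <- feature_matrix(beta, "beta")
  if (!anyNA(m)) return(beta)
  obs <- !is.na(m)
  if (any(rowSums(obs) == 0)) {
    abort(sprintf("probe(s) fully missing, cannot impute: %s",
                  paste(head(rownames(m)[rowSums(obs) == 0], 5), collapse = ", ")))
  }
  # pairwise mean squared difference over shared observed samples, via
  # masked cross-products (zero-filled values X0 and the indicator O):
  # sum_shared (x_i - x_r)^2 = X0^2 O' + O (X0^2)' - 2 X0 X0'
  x0 <- m
  x0[!obs] <- 0
  om <- obs * 1
  sq <- x0^2
  ss <- sq %*% t(om) + om %*% t(sq) - 2 * x0 %*% t(x0)
  n_shared <- om %*% t(om)
  d2 <- ss / n_shared
  d2[n_shared == 0] <- Inf
  diag(d2) <- Inf

  obs_by_col <- apply(obs, 2, which, simplify = FALSE)
  na_rows <- which(rowSums(!obs) > 0)
  for (i in na_rows) {
    ord <- order(d2[i, ])
    ord <- ord[is.finite(d2[i, ord])]
    for (j in which(!obs[i, ])) {
      donors <- intersect(ord, obs_by_col[[j]])
      if (length(donors) == 0) {
        m[i, j] <- mean(m[i, ], na.rm = TRUE)
        next
      }
      nn <- donors[seq_len(min(k, length(donors)))]
      m[i, j] <- mean(m[nn, j])
    }
  }
  out <- beta
  out[, -1] <- as_tibble(m)
  out
}

#' Assign probes to gene promoter windows
#'
#' The promoter is the strand-aware window from `upstream` bp before to
#' `downstream` bp after the transcription start site, endpoints
#' inclusive. For a `+`-strand gene the window is
#' `[tss - upstream, tss + downstream]` in genomic coordinates; for a
#' `-`-strand gene it is `[tss - downstream, tss + upstream]`. Probes
#' falling in no gene's window are dropped; a probe inside several
#' overlapping windows yields one assignment per gene.
#'
#' @param annotation tibble with `probe_id`, `pos`, `strand`, `gene`,
#'   `tss` (1-based coordinates).
#' @param upstream,downstream window half-extents in bp.
#' @return tibble `probe_id`, `gene`, `offset` where `offset` is the
#'   signed distance from the TSS in the direction of transcription
#'   (negative = upstream).
#' @export
assign_promoter_probes <- function(annotation, upstream = 1500, downstream = 500) {
  bad <- !annotation$strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("unknown strand for probe(s): %s",
                  paste(head(annotation$probe_id[bad], 5), collapse = ", ")))
  }
  annotation |>
    mutate(offset = ifelse(.data$strand == "+",
                           .data$pos - .data$tss,
                           .data$tss - .data$pos)) |>
    filter(.data$offset >= -upstream, .data$offset <= downstream) |>
    select("probe_id", "gene", "offset")
}

#' Convert FPKM to TPM
#'
#' Per sample, `tpm = fpkm / sum(fpkm) * 1e6`, so every output column
#' sums to one million and within-sample rank order is unchanged.
#'
#' @param expr tibble: first column gene id, remaining columns FPKM per
#'   sample (non-negative, no missing values).
#' @return tibble of TPM values, same shape.
#' @export
fpkm_to_tpm <- function(expr) {
  m <- feature_matrix(expr, "expression")
  if (anyNA(m) || any(m < 0)) abort("expression must be non-negative with no NA")
  cs <- colSums(m)
  if (any(cs == 0)) {
    abort(sprintf("all-zero expression column(s): %s",
                  paste(colnames(m)[cs == 0], collapse = ", ")))
  }
  out <- expr
  out[, -1] <- as_tibble(sweep(m, 2, cs, "/") * 1e6)
  out
}
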