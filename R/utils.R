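# Shared small helpers: logit-scale transforms for beta values and
# validation of the (values, pairing) tabular contract used throughout.

#' Beta-value / M-value transforms
#'
#' A beta value is the methylated fraction at a CpG, in \[0,1\]; the
#' M-value is its base-2 logit, `log2(beta / (1 - beta))`. Noise models
#' and variance-stabilised tests operate on the M scale.
#'
#' @param beta numeric vector of methylation fractions in (0, 1).
#' @param m numeric vector of M-values.
#' @param eps betas are clamped to `[eps, 1 - eps]` before the logit so
#'   boundary values stay finite.
#' @return numeric vector of the same length.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))
#' m_to_beta(beta_to_m(0.25))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  beta <- pmin(pmax(beta, eps), 1 - eps)
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

# Extract the numeric value matrix from a feature table whose first column
# holds feature identifiers and whose remaining columns are samples.
feature_matrix <- function(tbl, what = "feature table") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort(sprintf("%s must be a data frame with an id column plus >=1 sample column", what))
  }
  ids <- as.character(tbl[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("%s has duplicated feature ids", what))
  }
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("%s sample columns must be numeric", what))
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_col) {
  out <- as_tibble(m)
  out <- tibble(!!id_col := rownames(m)) |> dplyr::bind_cols(out)
  out
}

# Validate a pairing table: one tumour and one normal sample per pair id.
check_pairing <- function(pairing, sample_ids = NULL) {
  need <- c("sample_id", "pair_id", "group")
  if (!all(need %in% names(pairing))) {
    abort("pairing must have columns sample_id, pair_id, group")
  }
  if (!all(pairing$group %in% c("tumor", "normal"))) {
    abort("pairing$group must be 'tumor' or 'normal'")
  }
  bad <- pairing |>
    count(.data$pair_id, .data$group) |>
    filter(.data$n != 1L)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "pair id(s) without exactly one tumor and one normal sample: %s",
      paste(unique(bad$pair_id), collapse = ", ")
    ))
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(pairing$sample_id, sample_ids)
    if (length(missing) > 0) {
      abort(sprintf("pairing samples absent from matrix: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  invisible(pairing)
}

# Split a value matrix into tumour and normal sub-matrices with columns
# aligned by pair id.
paired_split <- function(m, pairing) {
  check_pairing(pairing, colnames(m))
  wide <- pairing |>
    select("sample_id", "pair_id", "group") |>
    tidyr::pivot_wider(names_from = "group", values_from = "sample_id")
  list(
    tumor  = m[, wide$tumor, drop = FALSE],
    normal = m[, wide$normal, drop = FALSE],
    pair_id = wide$pair_id
  )
}
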