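# Shared hypergeometric core for the neighbourhood-enrichment statistic and
# gene-set over-representation. Implemented by direct summation of
# log-binomial terms so both callers use the identical tail.

#' Hypergeometric enrichment p-value
#'
#' Probability, under sampling without replacement, of seeing `a` or more
#' "special" items among `m` draws from an urn of `N` items of which `K`
#' are special — the one-sided Fisher exact test on the 2x2 table
#' `[[a, m - a], [K - a, N - m - K + a]]`. With
#' `alternative = "two.sided"` the p-value follows the exact-test
#' convention of summing the probabilities of all tables at least as
#' extreme (point probability no larger than the observed one).
#'
#' Terms are accumulated as `exp(lchoose(...))` sums, so results are exact
#' to double precision and never rely on a normal approximation.
#'
#' @param a observed count of special items among the draws.
#' @param m number of draws (e.g. the size of a gene's neighbourhood, or
#'   the query list size).
#' @param K number of special items in the population.
#' @param N population size.
#' @param alternative `"greater"` for the enrichment tail `P(X >= a)`,
#'   `"two.sided"` for the exact-test two-sided p-value.
#' @return numeric vector of p-values in `(0, 1]`; arguments are recycled
#'   to a common length.
#' @examples
#' hyper_enrichment_p(3, 4, 5, 20)
#' # equals sum(dhyper(3:4, 5, 15, 4))
#' @export
hyper_enrichment_p <- function(a, m, K, N,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(m), length(K), length(N))
  a <- rep_len(as.numeric(a), n)
  m <- rep_len(as.numeric(m), n)
  K <- rep_len(as.numeric(K), n)
  N <- rep_len(as.numeric(N), n)
  if (any(is.na(a) | is.na(m) | is.na(K) | is.na(N))) {
    abort("hyper_enrichment_p: NA arguments")
  }
  if (any(a < 0 | m < 0 | K < 0 | N < 0 | m > N | K > N | a > pmin(m, K))) {
    abort("hyper_enrichment_p: need 0 <= a <= min(m, K) and m, K <= N")
  }
  vapply(seq_len(n), function(i) {
    hyper_p_one(a[i], m[i], K[i], N[i], alternative)
  }, numeric(1))
}

hyper_p_one <- function(a, m, K, N, alternative) {
  lo <- max(0, m + K - N)
  hi <- min(m, K)
  if (alternative == "greater" && a <= lo) return(1)
  x <- lo:hi
  lp <- lchoose(K, x) + lchoose(N - K, m - x) - lchoose(N, m)
  if (alternative == "greater") {
    keep <- x >= a
  } else {
    # all tables with point probability <= observed, with a small relative
    # slack for ties computed in floating point
    keep <- lp <= lp[x == a] + log(1 + 1e-7)
  }
  mx <- max(lp[keep])
  min(1, exp(mx) * sum(exp(lp[keep] - mx)))
}
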