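# Kaplan-Meier estimation and the two-group log-rank test, implemented
# from first principles, plus the median expression split that defines
# the groups.

#' Split samples into high/low expression groups
#'
#' `high` is strictly above the median, `low` at or below it (ties go
#' low). Constant expression cannot be split and is an error.
#'
#' @param values named numeric vector of per-sample expression, or a
#'   two-column data frame (sample id, value).
#' @return tibble `sample_id`, `value`, `group` (`"high"`/`"low"`).
#' @export
split_by_expression <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(ncol(values) >= 2)
    v <- setNames(as.numeric(values[[2]]), as.character(values[[1]]))
  } else {
    v <- values
    if (is.null(names(v))) names(v) <- paste0("s", seq_along(v))
  }
  if (length(v) < 2) abort("need >= 2 samples to split")
  med <- median(v)
  if (all(v == v[1])) abort("cannot split: constant expression")
  grp <- ifelse(v > med, "high", "low")
  inform(sprintf("median split: %d high, %d low", sum(grp == "high"),
                 sum(grp == "low")))
  tibble(sample_id = names(v), value = unname(v), group = unname(grp))
}

check_survival_records <- function(records) {
  need <- c("time", "event")
  if (!all(need %in% names(records))) {
    abort("survival records need columns time and event")
  }
  if (nrow(records) == 0) abort("no survival records")
  if (any(records$time < 0)) abort("negative survival time")
  if (!all(records$event %in% c(0, 1))) abort("event must be 0 or 1")
  invisible(records)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, with
#' `d_i` events and `n_i` at risk at `t_i`; right-continuous, `S(0) = 1`.
#' If `records` has a `group` column the estimate is computed per group.
#'
#' @param records tibble with `time` (non-negative), `event` (1 = event,
#'   0 = censored) and optionally `group`.
#' @return tibble of class `km_fit`: `group` (if present), `time`
#'   (distinct observed times), `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_estimate <- function(records) {
  check_survival_records(records)
  one_group <- function(d) {
    tab <- d |>
      group_by(.data$time) |>
      summarise(n_event = sum(.data$event == 1),
                n_censor = sum(.data$event == 0), .groups = "drop") |>
      arrange(.data$time)
    n_total <- nrow(d)
    tab$n_risk <- n_total - dplyr::lag(cumsum(tab$n_event + tab$n_censor),
                                       default = 0)
    tab$survival <- cumprod(1 - tab$n_event / tab$n_risk)
    tab |> select("time", "n_risk", "n_event", "n_censor", "survival")
  }
  out <- if ("group" %in% names(records)) {
    records |>
      group_by(.data$group) |>
      dplyr::group_modify(~ one_group(.x)) |>
      ungroup()
  } else {
    one_group(records)
  }
  class(out) <- c("km_fit", class(out))
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time, compares the observed events in group A
#' with the expectation under a common hazard,
#' `e_A = d * n_A / n`, accumulating the hypergeometric variance
#' `v = d (n_A/n)(1 - n_A/n)(n - d)/(n - 1)`; the statistic
#' `U^2 / V ~ chi-square(1)` under the null. Zero total variance (e.g.
#' no events) yields p = 1 with a warning.
#'
#' @param records tibble with `time`, `event` and a two-level `group`
#'   column.
#' @return object of class `logrank_test`: list with `statistic`, `df`,
#'   `p_value`, `observed`/`expected` per group and `n` per group.
#'   [tidy()] gives the per-group table, [glance()] the one-row summary.
#' @export
logrank_test <- function(records) {
  check_survival_records(records)
  if (!"group" %in% names(records)) abort("records need a group column")
  groups <- sort(unique(records$group))
  if (length(groups) != 2) abort("log-rank test needs exactly 2 groups")
  if (sum(records$event) == 0) abort("log-rank test needs >= 1 event")
  gA <- records$group == groups[1]
  times <- sort(unique(records$time[records$event == 1]))
  U <- 0; V <- 0; oA <- 0; eA <- 0
  for (t in times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    nA <- sum(at_risk & gA)
    d <- sum(records$time == t & records$event == 1)
    dA <- sum(records$time == t & records$event == 1 & gA)
    e <- d * nA / n
    U <- U + (dA - e)
    oA <- oA + dA
    eA <- eA + e
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  if (V == 0) {
    warn("zero log-rank variance; p set to 1")
    chisq <- 0; p <- 1
  } else {
    chisq <- U^2 / V
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  d_tot <- sum(records$event)
  structure(list(
    statistic = chisq, df = 1L, p_value = p,
    groups = tibble(
      group = groups,
      n = c(sum(gA), sum(!gA)),
      observed = c(oA, d_tot - oA),
      expected = c(eA, d_tot - eA)
    )
  ), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group log-rank test\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  cat(sprintf("chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname logrank_test
#' @param x a `logrank_test` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.logrank_test <- function(x, ...) x$groups

#' @rdname logrank_test
#' @exportS3Method generics::glance
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Plot a Kaplan-Meier fit
#'
#' Right-continuous step curves starting at S(0) = 1, censoring marks as
#' crosses, one colour per group.
#'
#' @param object a [km_estimate()] result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) {
  d <- as_tibble(object)
  if (!"group" %in% names(d)) d$group <- "all"
  start <- d |> distinct(.data$group) |>
    mutate(time = 0, survival = 1, n_event = 0L, n_censor = 0L)
  steps <- dplyr::bind_rows(start, d) |> arrange(.data$group, .data$time)
  ggplot2::ggplot(steps,
                  ggplot2::aes(.data$time, .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = steps |> filter(.data$n_censor > 0),
                        shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "S(t)", colour = NULL) +
    ggplot2::theme_minimal()
}
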