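# Median expression split, the Kaplan-Meier product-limit estimator and
# the two-group log-rank test, checked against the survival package as
# an independent oracle.

test_that("split_by_expression sends ties to the low group", {
  suppressMessages({
    even <- split_by_expression(setNames(1:10, paste0("s", 1:10)))
    expect_equal(sum(even$group == "high"), 5)
    expect_equal(sum(even$group == "low"), 5)

    ties <- split_by_expression(setNames(c(1, 5, 5, 9), paste0("s", 1:4)))
    expect_equal(ties$group, c("low", "low", "low", "high"))

    two <- split_by_expression(data.frame(id = c("a", "b"), v = c(1, 2)))
    expect_equal(sort(two$group), c("high", "low"))
  })
  expect_error(suppressMessages(split_by_expression(rep(3, 5))), "constant")
})

test_that("KM estimator reproduces textbook product-limit values", {
  # all censored: flat at 1
  flat <- km_estimate(tibble::tibble(time = c(2, 5, 9), event = 0))
  expect_true(all(flat$survival == 1))

  # three events, no censoring
  km <- km_estimate(tibble::tibble(time = 1:3, event = 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # mixed hand-computed table: two events at t=1 (6 at risk), censoring
  # at 2, an event at 3 (3 at risk), censoring at 4, an event at 6
  # (1 at risk)
  rec <- tibble::tibble(time = c(1, 1, 2, 3, 4, 6),
                        event = c(1, 1, 0, 1, 0, 1))
  km2 <- km_estimate(rec)
  expect_equal(km2$survival[km2$time == 1], 4 / 6)
  expect_equal(km2$survival[km2$time == 3], 4 / 6 * 2 / 3)
  expect_equal(km2$survival[km2$time == 6], 0)
  expect_error(km_estimate(tibble::tibble(time = -1, event = 1)), "negative")
})

test_that("KM agrees with survival::survfit on random fixtures", {
  withr::with_seed(23, {
    for (i in 1:5) {
      rec <- tibble::tibble(time = round(rexp(40, 0.1), 1),
                            event = rbinom(40, 1, 0.7))
      km <- km_estimate(rec)
      sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
      expect_equal(km$time, sf$time)
      expect_equal(km$survival, sf$surv, tolerance = 1e-12)
      expect_equal(km$n_risk, sf$n.risk)
      # S(t) is non-increasing within [0, 1]
      expect_true(all(diff(km$survival) <= 1e-12))
      expect_true(all(km$survival >= 0 & km$survival <= 1))
    }
  })
})

test_that("log-rank statistic matches a hand-worked 8-subject table", {
  rec <- tibble::tibble(
    time  = c(1, 2, 3, 4, 2, 3, 5, 6),
    event = c(1, 1, 0, 1, 1, 0, 1, 0),
    group = rep(c("A", "B"), each = 4)
  )
  # manual expected counts for group A at event times 1, 2, 4, 5:
  # t=1: d=1, nA=4, n=8, e=0.5, v=0.25
  # t=2: d=2, nA=3, n=7, e=6/7, v=2*(3/7)*(4/7)*(5/6)
  # t=4: d=1, nA=1, n=3, e=1/3, v=(1/3)*(2/3)
  # t=5: d=1, nA=0, n=2, e=0,   v=0
  eA <- 0.5 + 6 / 7 + 1 / 3 + 0
  V <- 0.25 + 2 * (3 / 7) * (4 / 7) * (5 / 6) + 2 / 9 + 0
  U <- 3 - eA
  lr <- logrank_test(rec)
  expect_equal(lr$statistic, U^2 / V, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(U^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lr$groups$observed, c(3, 2))
  expect_equal(lr$groups$expected, c(eA, 5 - eA), tolerance = 1e-12)

  gl <- glance(lr)
  expect_equal(gl$p_value, lr$p_value)
  expect_equal(nrow(tidy(lr)), 2)
})

test_that("log-rank agrees with survival::survdiff and is symmetric", {
  withr::with_seed(29, {
    for (i in 1:5) {
      rec <- tibble::tibble(
        time = round(rexp(60, 0.08), 1),
        event = rbinom(60, 1, 0.8),
        group = rep(c("x", "y"), 30)
      )
      lr <- logrank_test(rec)
      sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = rec)
      expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-10)
      flipped <- logrank_test(rec |>
                                dplyr::mutate(group = ifelse(group == "x", "y", "x")))
      expect_equal(flipped$statistic, lr$statistic, tolerance = 1e-12)
      expect_equal(flipped$p_value, lr$p_value, tolerance = 1e-12)
    }
  })
})

test_that("identical groups give chi-square 0 and duplicated-arm p 1", {
  one_arm <- tibble::tibble(time = c(1, 2, 4, 7), event = c(1, 1, 0, 1))
  rec <- dplyr::bind_rows(one_arm |> dplyr::mutate(group = "A"),
                          one_arm |> dplyr::mutate(group = "B"))
  lr <- logrank_test(rec)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
})

test_that("a strong simulated hazard ratio is detected", {
  cfg <- sim_config(hazard_ratio = 3, censor_rate = 0.2, seed = 1)
  groups <- tibble::tibble(sample_id = paste0("s", 1:400),
                           group = rep(c("high", "low"), each = 200))
  surv <- simulate_survival(groups, cfg)
  expect_lt(glance(logrank_test(surv))$p_value, 0.001)
  # high-hazard group dies faster
  km <- km_estimate(surv)
  med_high <- min(km$time[km$group == "high" & km$survival <= 0.5])
  med_low <- min(km$time[km$group == "low" & km$survival <= 0.5])
  expect_lt(med_high, med_low)
})

test_that("null hazard yields approximately uniform log-rank p-values", {
  cfg0 <- sim_config(hazard_ratio = 1, censor_rate = 0.2)
  groups <- tibble::tibble(sample_id = paste0("s", 1:60),
                           group = rep(c("high", "low"), each = 30))
  pvals <- vapply(1:200, function(s) {
    cfg <- sim_config(hazard_ratio = 1, censor_rate = 0.2, seed = s)
    glance(logrank_test(simulate_survival(groups, cfg)))$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("all-censored cohorts stay flat at 1 and refuse the log-rank test", {
  cfg <- sim_config(censor_rate = 1, seed = 4)
  groups <- tibble::tibble(sample_id = paste0("s", 1:40),
                           group = rep(c("high", "low"), 20))
  surv <- simulate_survival(groups, cfg)
  expect_true(all(surv$event == 0))
  expect_true(all(km_estimate(surv)$survival == 1))
  expect_error(logrank_test(surv), ">= 1 event")
})
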