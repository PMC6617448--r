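# PPI container, subnet extraction, degree distributions and the
# neighbourhood Fisher hub statistic.

test_that("ppi_network deduplicates edges and drops self-loops", {
  edges <- tibble::tibble(from = c("A", "B", "A"), to = c("B", "A", "A"))
  expect_message(net <- ppi_network(edges), "self-loop")
  expect_equal(sort(net$nodes), c("A", "B"))
  expect_equal(igraph::ecount(net$graph), 1)
})

test_that("read_ppi parses edge lists and reports malformed lines", {
  f <- withr::local_tempfile(lines = c("A\tB\t0.9", "B\tC\t0.5", "A\tC\t0.1"))
  net <- read_ppi(f)
  expect_equal(sort(net$nodes), c("A", "B", "C"))
  expect_equal(igraph::ecount(net$graph), 3)

  bad <- withr::local_tempfile(lines = c("A\tB", "oops"))
  expect_error(read_ppi(bad), "line 2")
  empty <- withr::local_tempfile(lines = character(0))
  expect_error(read_ppi(empty), "empty network")
})

test_that("simulated PPI round-trips through the edge-list reader", {
  cfg <- small_sim_config(seed = 2)
  sim <- simulate_methylation_expression(cfg)
  ppi <- simulate_ppi(cfg, sim$truth)
  f <- withr::local_tempfile()
  readr::write_tsv(ppi$edges, f, col_names = FALSE)
  net <- read_ppi(f)
  expect_equal(length(net$nodes), cfg$ppi_n_nodes)
  expect_equal(igraph::ecount(net$graph), nrow(ppi$edges))
})

test_that("extract_subnet reports mapping counts and mean degree", {
  net <- ppi_network(tibble::tibble(from = c("A", "D"), to = c("B", "E")))
  res <- extract_subnet(net, c("A", "B", "C"))
  expect_equal(res$report$n_mapped, 2)        # C is absent from the network
  expect_equal(res$report$n_with_interactions, 2)
  expect_equal(res$report$mean_degree, 1)

  # the worked three-gene example, with C present but isolated
  net2 <- ppi_network(tibble::tibble(from = "A", to = "B"), nodes = "C")
  res2 <- extract_subnet(net2, c("A", "B", "C"))
  expect_equal(res2$report$n_mapped, 3)
  expect_equal(res2$report$n_with_interactions, 2)
  expect_equal(res2$report$mean_degree, 2 / 3)

  none <- extract_subnet(net, c("X", "Y"))
  expect_equal(none$report$n_mapped, 0)

  all_in <- extract_subnet(net, net$nodes)
  expect_equal(igraph::ecount(all_in$subnet$graph), igraph::ecount(net$graph))
})

test_that("degree_distribution counts exactly, isolates included", {
  star <- ppi_network(tibble::tibble(from = "hub", to = paste0("leaf", 1:4)))
  expect_equal(degree_distribution(star),
               tibble::tibble(degree = c(1L, 4L), n_nodes = c(4L, 1L)),
               ignore_attr = TRUE)

  iso <- ppi_network(tibble::tibble(from = "A", to = "B"), nodes = "C")
  expect_equal(degree_distribution(iso)$degree, c(0L, 1L))

  cfg <- small_sim_config(seed = 5)
  sim <- simulate_methylation_expression(cfg)
  ppi <- simulate_ppi(cfg, sim$truth)
  net <- ppi_network(ppi$edges)
  dist <- degree_distribution(net)
  # independent recount straight from the edge list
  recount <- table(table(c(ppi$edges$from, ppi$edges$to)))
  expect_equal(setNames(dist$n_nodes, dist$degree),
               setNames(as.integer(recount), names(recount)))
  expect_equal(sum(dist$n_nodes), length(net$nodes))
})

test_that("neighborhood_fisher builds the right contingency per node", {
  # hand fixture: hub with neighbours e1, e2, n1; eies = {e1, e2, hub}
  edges <- tibble::tibble(from = c("hub", "hub", "hub", "n1"),
                          to = c("e1", "e2", "n1", "n2"))
  net <- ppi_network(edges)
  stats <- neighborhood_fisher(net, c("e1", "e2", "hub"),
                               alternative = "greater")
  row <- stats[stats$gene == "hub", ]
  expect_equal(row$a, 2L)
  expect_equal(row$b, 1L)
  expect_equal(row$K, 2L)   # focal gene excluded from K
  expect_equal(row$N, 5L)
  expect_equal(row$neighborhood_frac, 2 / 3)
  # oracle: P(X >= 2), X ~ Hypergeom(N = 5, K = 2, m = 3)
  expect_equal(row$fisher_p, sum(dhyper(2, 2, 3, 3)), tolerance = 1e-12)

  # a node with no EI/ES neighbours keeps the whole upper tail: p = 1
  row_n2 <- stats[stats$gene == "n2", ]
  expect_equal(row_n2$a, 0L)
  expect_equal(hyper_enrichment_p(0, 1, 3, 5, "greater"), 1)

  # degree-0 nodes report p = 1 without testing
  iso <- ppi_network(edges, nodes = "lonely")
  st <- neighborhood_fisher(iso, "e1", genes = "lonely")
  expect_equal(st$fisher_p, 1)
  expect_equal(st$a, 0L)

  expect_warning(neighborhood_fisher(net, c("e1", "ghost")), "not in the network")
  expect_error(neighborhood_fisher(net, "e1", genes = "ghost"), "not in network")
})

test_that("call_hubs applies BH FDR and the neighbour-count floor", {
  stats <- tibble::tibble(
    gene = paste0("g", 1:4),
    a = c(10L, 3L, 8L, 0L),
    b = c(5L, 1L, 100L, 9L),
    K = 50L, N = 1000L,
    neighborhood_frac = c(10 / 15, 3 / 4, 8 / 108, 0),
    fisher_p = c(1e-8, 1e-6, 0.2, 1)
  )
  out <- call_hubs(stats)
  expect_equal(out$fdr, p.adjust(sort(stats$fisher_p), "BH"))
  expect_true(out$is_hub[out$gene == "g1"])
  expect_false(out$is_hub[out$gene == "g2"])  # significant but < 5 hits
  expect_false(any(out$is_hub[out$gene %in% c("g3", "g4")]))
  expect_equal(out$gene, paste0("g", c(1, 2, 3, 4)))  # sorted by p

  expect_false(any(call_hubs(stats, fdr_max = 0)$is_hub))

  # n_tests inflates the correction when only a subset is supplied
  sub <- call_hubs(stats[1, ], n_tests = 100)
  expect_equal(sub$fdr, stats$fisher_p[1] * 100)
})

test_that("random labels do not produce spurious hub calls", {
  cfg <- small_sim_config(seed = 31, n_hubs_planted = 0)
  sim <- simulate_methylation_expression(cfg)
  ppi <- simulate_ppi(cfg, sim$truth)
  net <- ppi_network(ppi$edges)
  false_calls <- sum(vapply(1:5, function(s) {
    labels <- withr::with_seed(s, sample(net$nodes, 30))
    stats <- neighborhood_fisher(net, labels)
    sum(call_hubs(stats)$is_hub)
  }, numeric(1)))
  expect_lte(false_calls, 1)
})
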