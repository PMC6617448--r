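# The synthetic cohort generator: reproducibility, value ranges, planted
# effect sizes, methylation-expression coupling and the planted-hub
# construction.

test_that("identical configs reproduce bit-identical cohorts", {
  cfg <- small_sim_config(seed = 77)
  a <- simulate_methylation_expression(cfg)
  b <- simulate_methylation_expression(cfg)
  expect_identical(a, b)
  pa <- simulate_ppi(cfg, a$truth)
  pb <- simulate_ppi(cfg, b$truth)
  expect_identical(pa, pb)
  groups <- tibble::tibble(sample_id = paste0("s", 1:20),
                           group = rep(c("high", "low"), 10))
  expect_identical(simulate_survival(groups, cfg),
                   simulate_survival(groups, cfg))
  # a different seed changes the data
  expect_false(identical(
    a$beta, simulate_methylation_expression(small_sim_config(seed = 78))$beta))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(n_ei_planted = 60, n_es_planted = 60, n_genes = 100),
               "n_ei_planted")
  expect_error(sim_config(beta_shift = 1.5), "beta_shift")
  expect_error(sim_config(ppi_n_nodes = 10, n_genes = 100), "ppi_n_nodes")
  expect_error(sim_config(ppi_attach_m = 0), "ppi_attach_m")
  expect_error(sim_config(censor_rate = 2), "censor_rate")
  expect_error(sim_config(hazard_ratio = 0), "hazard_ratio")
  cfg_bad <- small_sim_config(seed = 1, hub_ei_frac = 1, hub_degree = 100)
  sim <- simulate_methylation_expression(cfg_bad)
  expect_error(simulate_ppi(cfg_bad, sim$truth), "hub_ei_frac")
})

test_that("betas stay inside [0, 1] and NA masking matches the config", {
  cfg <- small_sim_config(seed = 3, na_frac = 0.05)
  sim <- simulate_methylation_expression(cfg)
  vals <- as.matrix(sim$beta[, -1])
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  expect_equal(mean(is.na(vals)), 0.05, tolerance = 0.01)
  expect_true(all(as.matrix(sim$expr[, -1]) > 0))
})

test_that("a point-mass probe distribution gives one probe per gene", {
  cfg <- small_sim_config(seed = 2,
                          probes_per_promoter_dist = c(1, rep(0, 9)))
  sim <- simulate_methylation_expression(cfg)
  expect_equal(nrow(sim$annotation), cfg$n_genes)
  expect_equal(unname(table(sim$annotation$gene)), rep(1L, cfg$n_genes),
               ignore_attr = TRUE)
  # and every simulated probe lies inside its promoter window
  asg <- assign_promoter_probes(sim$annotation)
  expect_equal(nrow(asg), nrow(sim$annotation))
})

test_that("planted genes carry the configured beta and expression shifts", {
  cfg <- sim_config(n_genes = 500, n_pairs = 21, n_ei_planted = 30,
                    n_es_planted = 30, na_frac = 0, seed = 11)
  sim <- simulate_methylation_expression(cfg)
  bm <- as.matrix(sim$beta[, -1]); rownames(bm) <- sim$beta$probe_id
  em <- log2(as.matrix(sim$expr[, -1])); rownames(em) <- sim$expr$gene
  tum <- sim$pairing$sample_id[sim$pairing$group == "tumor"]
  nor <- sim$pairing$sample_id[sim$pairing$group == "normal"]
  probe_gene <- setNames(sim$annotation$gene, sim$annotation$probe_id)
  lab <- setNames(sim$truth$label, sim$truth$gene)

  d_beta <- rowMeans(bm[, tum]) - rowMeans(bm[, nor])
  probe_lab <- lab[probe_gene[rownames(bm)]]
  expect_equal(mean(d_beta[probe_lab == "EI"]), -cfg$beta_shift, tolerance = 0.05)
  expect_equal(mean(d_beta[probe_lab == "ES"]), cfg$beta_shift, tolerance = 0.05)
  expect_equal(mean(d_beta[probe_lab == "null"]), 0, tolerance = 0.02)

  d_expr <- rowMeans(em[, tum]) - rowMeans(em[, nor])
  expect_equal(mean(d_expr[lab[rownames(em)] == "EI"]), cfg$expr_log2fc,
               tolerance = 0.15)
  expect_equal(mean(d_expr[lab[rownames(em)] == "ES"]), -cfg$expr_log2fc,
               tolerance = 0.15)
  expect_equal(mean(d_expr[lab[rownames(em)] == "null"]), 0, tolerance = 0.1)
})

test_that("methylation and expression are negatively coupled per sample", {
  cfg <- sim_config(n_genes = 400, n_pairs = 21, n_ei_planted = 40,
                    n_es_planted = 0, na_frac = 0, seed = 13)
  sim <- simulate_methylation_expression(cfg)
  bm <- as.matrix(sim$beta[, -1]); rownames(bm) <- sim$beta$probe_id
  em <- log2(as.matrix(sim$expr[, -1])); rownames(em) <- sim$expr$gene
  tum <- sim$pairing$sample_id[sim$pairing$group == "tumor"]
  planted <- sim$truth$gene[sim$truth$label == "EI"]
  first_probe <- sim$annotation |>
    dplyr::distinct(gene, .keep_all = TRUE)
  # correlate within the tumour arm only, so the group shift cannot
  # create the correlation by itself: it must come from the shared
  # latent factor
  cors <- vapply(planted, function(g) {
    p <- first_probe$probe_id[first_probe$gene == g]
    cor(bm[p, tum], em[g, tum])
  }, numeric(1))
  expect_lt(mean(cors), -0.2)
})

test_that("preferential attachment with m = 1 yields a connected tree", {
  cfg <- sim_config(n_genes = 10, n_pairs = 2, n_ei_planted = 0,
                    n_es_planted = 0, ppi_n_nodes = 10, ppi_attach_m = 1,
                    n_hubs_planted = 0, seed = 5)
  sim <- simulate_methylation_expression(cfg)
  ppi <- simulate_ppi(cfg, sim$truth)
  expect_equal(nrow(ppi$edges), 9)
  g <- ppi_network(ppi$edges)
  expect_true(igraph::is_connected(g$graph))
})

test_that("planted hubs meet their EI/ES neighbourhood fraction", {
  cfg <- small_sim_config(seed = 7)
  sim <- simulate_methylation_expression(cfg)
  ppi <- simulate_ppi(cfg, sim$truth)
  net <- ppi_network(ppi$edges)
  planted <- sim$truth$gene[sim$truth$label != "null"]
  expect_length(ppi$planted_hubs, cfg$n_hubs_planted)
  for (h in ppi$planted_hubs) {
    nb <- igraph::neighbors(net$graph, h)$name
    expect_gte(mean(nb %in% planted), cfg$hub_ei_frac)
  }
  # planted hubs are not themselves planted EI/ES genes
  expect_length(intersect(ppi$planted_hubs, planted), 0)
})

test_that("simulated censoring matches the configured rate", {
  groups <- tibble::tibble(sample_id = paste0("s", 1:2000),
                           group = rep(c("high", "low"), 1000))
  surv <- simulate_survival(groups, sim_config(censor_rate = 0.3, seed = 21))
  expect_equal(mean(surv$event == 0), 0.3, tolerance = 0.04)
  expect_true(all(surv$time >= 0))
  none <- simulate_survival(groups, sim_config(censor_rate = 0, seed = 21))
  expect_true(all(none$event == 1))
})

test_that("write_simulation emits readable TSV files", {
  cfg <- small_sim_config(seed = 15)
  sim <- simulate_methylation_expression(cfg)
  sim$ppi <- simulate_ppi(cfg, sim$truth)
  dir <- withr::local_tempdir()
  files <- write_simulation(sim, dir)
  expect_true(all(file.exists(files)))
  back <- readr::read_tsv(files[["beta"]], show_col_types = FALSE)
  expect_equal(dim(back), dim(sim$beta))
  net <- read_ppi(files[["ppi"]])
  expect_equal(igraph::ecount(net$graph), nrow(sim$ppi$edges))
})
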