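# methylhub

Integrated analysis of paired tumour/normal DNA methylation and gene
expression, for researchers asking which genes a tumour switches on by
demethylating their promoters (epigenetically induced, **EI**) or
switches off by methylating them (epigenetically suppressed, **ES**) —
and which network genes concentrate that regulatory signal.

The pipeline, stage by stage:

1. **Preprocess** — filter 450K-style probes (cross-reactive, SNP,
   sex-chromosome, missingness > 70%), impute the rest by kNN, assign
   probes to strand-aware promoter windows (TSS −1500 bp … +500 bp),
   convert FPKM to TPM.
2. **Differential** — paired *t*-tests across matched pairs; DEGs at
   p < 0.05 and |log₂(median ratio)| > 1, DMPs at p < 0.05;
   direction-consistent promoter DMPs consolidate into DMGs.
3. **Integrate** — EI = expression up + promoter methylation down,
   ES = the converse, each confirmed by a significant negative
   beta–expression correlation across samples.
4. **Hub genes** — the core statistic. For a gene with *m* network
   neighbours, *a* of them EI/ES, against a PPI of *N* genes with *K*
   EI/ES members, Fisher's exact test on

   ```
   [ a      m − a         ]
   [ K − a  N − m − K + a ]
   ```

   BH-FDR over all tested nodes; hubs need FDR < 0.05 **and** ≥ 5
   EI/ES neighbours.
5. **Downstream** — hypergeometric over-representation of the EI/ES
   list on user-supplied gene sets with Jaccard ≥ 0.5 term-crosstalk
   edges; Kaplan–Meier curves and a log-rank test for high- vs
   low-expression groups of a hub gene (median split, ties low).

A synthetic-data module generates full cohorts — paired beta and
expression matrices with planted EI/ES genes coupled through a shared
latent factor, a scale-free PPI with planted hubs, survival times with
a known hazard ratio — plus truth tables, so every stage is testable
against ground truth without any external download.

## Worked example

```r
library(methylhub)
library(dplyr)

cfg <- sim_config(seed = 42)
cfg
#> <sim_config> 21 pairs, 2000 genes (10 EI + 10 ES planted), beta_shift 0.3, log2fc 2
#>   PPI 2000 nodes (m = 5), 4 hubs planted, hub_ei_frac 0.5; seed 42

sim <- simulate_methylation_expression(cfg)
ppi <- simulate_ppi(cfg, sim$truth)

res <- pipeline_config(beta = sim$beta, expr = sim$expr,
                       annotation = sim$annotation, ppi = ppi$edges,
                       pairing = sim$pairing) |>
  run_pipeline()

res$summary$counts
#> # A tibble: 1 × 2
#>    n_ei  n_es
#>   <int> <int>
#> 1    10    10

res$hubs |> filter(is_hub) |>
  select(gene, a, b, K, neighborhood_frac, fisher_p, fdr)
#> # A tibble: 4 × 7
#>   gene      a     b     K neighborhood_frac fisher_p      fdr
#>   <chr> <int> <int> <int>             <dbl>    <dbl>    <dbl>
#> 1 g0852     8     8    20               0.5 2.48e-13 1.24e-10
#> 2 g0243     8     8    20               0.5 2.48e-13 1.24e-10
#> 3 g1086     8     8    20               0.5 2.48e-13 1.24e-10
#> 4 g1569     8     8    20               0.5 2.48e-13 1.24e-10

sort(ppi$planted_hubs)
#> [1] "g0243" "g0852" "g1086" "g1569"
```

All 10 planted EI and 10 planted ES genes are confirmed, and the four
hub calls are exactly the four planted hubs: each has 16 neighbours of
which 8 (`a`) are EI/ES against only `K = 20` EI/ES genes among
`N = 2000`, so the Fisher p-values are vanishingly small and survive
BH correction with room to spare. `plot_hub_stats(res$hubs)`,
`plot_volcano(res$degs)` and `autoplot()` on a `km_estimate()` result
give the standard figures.

A thin command-line wrapper lives at `inst/cli/methylhub.R`
(`simulate` and `run` subcommands driven by YAML configs).

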