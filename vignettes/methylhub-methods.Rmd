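---
title: "Integrated promoter methylation and expression analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated promoter methylation and expression analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

methylhub integrates paired tumour/normal DNA-methylation (Illumina
450K-style beta values) and RNA-Seq expression matrices to find genes
whose expression change is plausibly driven by promoter methylation
change, and then asks which network genes sit at the centre of that
regulatory signal. This vignette explains each model, its assumptions,
the tunable parameters, and the design decisions taken where more than
one defensible choice existed.

## The analysis model, stage by stage

### Preprocessing

Beta values (methylated fraction per CpG, in $[0,1]$) are assumed
already normalised; the package does not touch raw array intensities.
Probe filtering removes cross-reactive probes (multi-mapping, per a
user-supplied flag), SNP-overlapping probes, sex-chromosome probes, and
probes whose missing fraction strictly exceeds `na_frac_max` (default
0.70 — "exceeds 70%" is read as $>$, so a probe missing in exactly 70%
of samples survives). Filtering is per probe, the standard 450K
practice; a per-sample cap is available as an option.

Remaining missing values are filled by k-nearest-neighbour imputation
(`k = 10`, the convention of the reference kNN imputers): each missing
entry becomes the mean of the `k` nearest probes by mean squared
difference over the samples both probes observe. Nearness is computed
in beta space; observed entries are returned bit-identical, and every
imputed value lies inside the range of its donors in that column.

The promoter is the strand-aware closed window from 1500 bp upstream to
500 bp downstream of the TSS, so the window is always 2000 bp wide. A
probe inside several overlapping windows is assigned to every such gene
— nothing in the promoter definition forbids shared probes. Coordinates
are 1-based inclusive throughout.

Expression arrives as FPKM and is rescaled per sample to TPM
($x_{ij} / \sum_i x_{ij} \times 10^6$), which preserves within-sample
rank order and makes columns comparable.

### Differential calling

Both views use a two-sided paired *t*-test across matched pairs; the
effect size is the ratio (expression) or difference (methylation) of
the tumour and normal **medians**, which is robust to single outlier
pairs. A DEG requires $p < 0.05$ and $|\log_2 \text{FC}| > 1$ (both
strict); a DMP requires $p < 0.05$.

Choices that the data alone could not fix:

* the expression *t*-test runs on $\log_2(\text{TPM} + 1)$ because the
  fold-change threshold is stated in log2 units and log-scale residuals
  are far closer to normal for expression data; raw-scale testing is a
  flag;
* the methylation *t*-test runs on beta values, for symmetry with the
  expression test; M-value testing (base-2 logit, more
  variance-stable near the boundaries) is a flag;
* a pseudocount of 1 TPM guards the ratio and the log against zero
  medians;
* genes with zero variance of paired differences get $p = 1$ and a
  flag, never NaN;
* **no multiple-testing correction** is applied at this stage: the
  screen is deliberately permissive, and FDR control enters once, at
  the hub statistic, where the inference actually lives.

Significant promoter DMPs are consolidated per gene: if all of a gene's
significant positions agree in sign, they are its *valid DMPs* and the
gene is a DMG with that direction; mixed-sign genes are *discordant*
and excluded from everything downstream.

### EI/ES classification

An epigenetically induced (EI) candidate is up in expression and down
in promoter methylation; epigenetically suppressed (ES) the converse.
Candidates must then pass a per-gene negative-correlation filter:
across samples, each valid DMP's beta values are correlated with the
gene's expression; the gene is confirmed only if every valid DMP
correlates negatively and the best correlation $p$ is below 0.05.

Open choices resolved here: Spearman correlation by default (the
beta/TPM scales are incommensurate and the relationship need not be
linear; Pearson is a flag); correlation across tumour and normal
samples jointly, which doubles $n$ at typical paired-cohort sizes
(tumour-only is a flag); two-sided $p$ with an explicit sign
requirement rather than a one-sided test; and the promoter consistency
rule is extended to the correlation stage — a gene whose valid DMPs
disagree in correlation sign is not confirmed.

### The neighbourhood Fisher hub statistic

For each network gene with $m$ neighbours, $a$ of them EI/ES, in a
background PPI of $N$ genes containing $K$ EI/ES genes, the statistic
is Fisher's exact test on
$\left[\begin{smallmatrix} a & m-a \\ K-a & N-m-K+a \end{smallmatrix}\right]$.
The focal gene never counts itself: it is excluded from its own
neighbourhood and from $K$ when it is itself EI/ES. The default is the
**two-sided** exact test — the convention under which all published
desk-checkable examples of this statistic reproduce exactly — with the
one-sided enrichment tail $P(X \ge a)$ available via
`alternative = "greater"`. The tail is computed by direct summation of
`lchoose` terms, shared verbatim with the over-representation module,
and is validated against independent combinatorial summation in the
test suite.

Hubs are the genes with Benjamini–Hochberg FDR $< 0.05$ computed over
all tested nodes **and** at least 5 EI/ES neighbours. The neighbour
floor matters: a degree-6 node with 4 EI/ES neighbours can reach a tiny
$p$ without being a biologically interesting hub. Both thresholds are
parameters (`fdr_max`, `min_hits`), as is the label set fed to the
statistic (EI∪ES by default; EI-only or ES-only by flag, since either
convention appears in practice).

### Over-representation and term crosstalk

Gene-set enrichment for the confirmed EI/ES list is the classical
hypergeometric upper tail over a user-supplied collection (GMT or long
tibble), BH-corrected; the universe defaults to all genes in the
expression matrix. Term databases themselves are out of scope. Pairs of
significant terms are connected when the Jaccard index of their gene
sets is at least `j_min = 0.5` (inclusive boundary), producing
enrichment-map-style crosstalk edges; rendering is left to graph tools.

### Survival

Samples split at the median of the chosen gene's expression, ties to
"low" (an explicit, reproducible rule standing in for the external web
tools' opaque "best cutoff" choices). The Kaplan–Meier product-limit
estimator and the two-group log-rank test are implemented from first
principles — $S(t)=\prod_{t_i \le t}(1-d_i/n_i)$ and
$\chi^2 = U^2/V$ with the usual hypergeometric variance — and are
checked against the survival package as an independent oracle in the
tests. Cox regression is deliberately out of scope: the package
compares curves, it does not model covariates.

## The synthetic cohort

Because the original cohort-scale inputs (450K matrices, RNA-Seq, a
reference PPI) cannot ship with a package, a generator produces
fixtures with the statistical structure every stage assumes, plus truth
tables, so the whole pipeline is testable against known ground truth.

Defaults describe a typical matched design: 21 tumour/normal pairs,
2000 genes, 1–10 promoter probes per gene with geometrically decaying
weights (most promoters carry a single informative probe), 10 planted
EI and 10 planted ES genes with a beta shift of 0.3 and an expression
$|\log_2\text{FC}|$ of 2, M-scale noise SD 0.5, 2% missing betas, 1%
cross-reactive and 1% SNP-flagged probes.

Generator mechanics worth knowing:

* **Methylation noise lives in M-value space** (base-2 logit) and is
  transformed back, so betas stay inside $(0,1)$ with no clipping
  artefacts at the boundaries.
* **The negative methylation–expression coupling is structural, not
  sorted in**: each planted gene×sample gets a latent normal draw that
  is added to the M-value and subtracted (scaled) from log2 expression;
  `coupling_frac = 0.5` of the noise variance is shared. Marginal
  distributions are untouched, and the correlation exists within the
  tumour arm alone, which is what the correlation filter actually
  tests.
* **The PPI is preferential-attachment** (Barabási–Albert, `m = 5` over
  2000 nodes) with gene names assigned to nodes in random order, so
  planted genes do not inherit systematically old, high-degree
  positions. Each planted hub (4 by default, chosen among non-planted
  genes) has its edges rewired to a 16-neighbour set containing half
  planted EI/ES genes; hub neighbourhood sizes are held moderate
  because a planted fraction of 0.5 must be satisfiable with only 20
  planted genes in the pool.
* **Survival times are exponential** — the simplest law in which
  `hazard_ratio` has an exact interpretation — with median 36 months in
  the low group; censoring times are exponential with the rate solved
  so each record is censored with probability `censor_rate` exactly.
* Identical configurations (including seed) reproduce bit-identical
  outputs; the three generators draw from distinct seed streams derived
  from the one seed.

What the generator does **not** emulate: Infinium type-I/II probe
chemistry and dye bias, detection p-values, copy-number contamination,
tumour purity, batch structure, and the long-range correlation of
methylation along the genome. Passing tests therefore demonstrate that
the pipeline's inference is correct when its model assumptions hold,
not that those assumptions hold in any particular cohort.

## Validation strategy and problem sizes

The test suite runs at sizes chosen to make each check sharp but quick:
the hypergeometric core is swept exhaustively over all $(K, m, a)$ for
$N \le 40$ and densely (random $(K,m)$ strata, exhaustive in $a$) up to
$N = 200$, against direct combinatorial summation at $10^{-12}$;
planted-structure recovery and hub calling are averaged over 20
simulation seeds at the default cohort scale; null calibration uses a
2000-gene effect-free cohort and 20 random-label seeds on the network
side. On one CPU the whole suite takes a few minutes.

## Known limitations

* The paired *t*-test assumes roughly normal paired differences;
  heavy-tailed expression noise will inflate the DEG stage's error
  rates (by design there is no moderation/shrinkage at that stage).
* The correlation filter needs variation: a gene or probe constant
  across samples is dropped with a message rather than guessed at.
* The hub statistic conditions on the observed network; edge
  uncertainty and study bias in PPI databases propagate directly into
  it. Confidence-weighted edges are out of scope.
* `extract_subnet` reports the induced EI/ES subgraph but hubs are
  tested against the full background network — an isolated EI gene
  still contributes to $K$.
* The KM/log-rank arm compares two groups defined by one gene at a
  time; no multivariable adjustment is attempted.
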