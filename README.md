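# genediv

Within-gene phylotype diversity dynamics for functional genes in time-series
metagenomes.

## The problem

A single ecosystem function — say nitrate reduction — is typically encoded by
many coexisting sequence variants of the same gene family, carried by
different organisms. The number of those variants, their evenness, and how
much they replace one another as conditions change determine how robust the
function is to environmental shifts: a family maintained by *resistant*
phylotypes keeps the same carriers throughout, one maintained by *resilient*
phylotypes reshuffles its carriers, and a family with almost no within-gene
diversity is a potential single point of failure for the whole pathway.

`genediv` implements a gene-centric analysis of this within-gene diversity
for shotgun metagenome time series, validated end to end on a bundled
synthetic community generator with planted ground truth. It is aimed at
microbial ecologists who want the full chain — phylotype definition, read
recruitment, marker normalization, diversity/turnover statistics,
environmental regressions — as reproducible, testable R functions.

## What it computes

* **Phylotypes**: greedy centroid clustering of protein sequences at a
  global-alignment identity threshold (default 90% amino-acid identity,
  Needleman–Wunsch under BLOSUM62, gaps counted in the denominator), plus a
  UPGMA guide tree on `1 − identity` for heatmap row ordering.
* **Abundances**: best-hit read recruitment (k-mer seeded, ≥95% nucleotide
  identity), RPKM = `count / (len/1000) / (libsize/1e6)`, per-capita gene
  abundance = family RPKM / single-copy-marker RPKM (the fraction of
  individuals carrying the gene), and phylotype relative-abundance matrices.
* **Diversity surfaces**: per-sample and cumulative richness and inverse
  Simpson (`1/Σp²`) with delta-from-initial series; temporal turnover as the
  mean over phylotypes of the variance of relative abundance across time;
  Bray–Curtis dissimilarity (`Σ|u−v| / Σ(u+v)`) and its distance-decay slope
  over time lag.
* **Inference**: first-principles Welch's t, Levene's (mean- or
  median-centered), exact Mann–Whitney (full null distribution of U when
  `n1·n2 ≤ 400`, no ties), Pearson correlations, and OLS regression grids of
  gene metrics against environmental covariates, verified against
  independent reference implementations in the test suite.
* **Synthetic communities**: phylotype pools with planted identity bounds,
  softmax-of-random-walk abundance dynamics (`walk_sigma` controls
  turnover), an environmental series with a mid-season hydrologic shift, and
  single-end reads with substitution errors — everything needed to test the
  pipeline against known truth.

## Worked example

A small end-to-end run: three simulated families — a high-richness/stable
one, a lower-richness/volatile one, and a two-phylotype family — plus an
8-phylotype single-copy marker, 11 samples across a simulated hydrologic
shift:

```r
library(genediv)
pre <- regime_presets(11)
cfg <- default_config(
  reads_per_sample = 3000,
  families = list(
    narG_like  = modifyList(pre$narG_like,
                            list(regime = regime_params("resistant", 12, 11, 0.10))),
    nirKS_like = modifyList(pre$nirKS_like,
                            list(regime = regime_params("resilient", 8, 11, 0.80))),
    amoA_like  = pre$amoA_like),
  marker = modifyList(pre$rplB_like,
                      list(regime = regime_params("resistant", 10, 11, 0.10))))
res <- run_all(cfg, seed = 42, out_dir = "demo_out")
res$turnover
#>   gene_family phylotype_richness mean_abundance_variance
#> 1   narG_like                 12            0.0002527499
#> 2  nirKS_like                  8            0.0198491859
#> 3   amoA_like                  2            0.0233953872
#> 4      marker                 10            0.0003971852
round(rowMeans(res$per_capita), 3)
#>  narG_like nirKS_like  amoA_like
#>      0.279      0.399      0.148
```

Reading the output: clustering recovered exactly the planted 12/8/2/10
phylotypes from the read data; the stable (`walk_sigma = 0.10`) family shows
a mean abundance variance two orders of magnitude below the volatile
(`walk_sigma = 0.80`) one — the resistant-versus-resilient contrast the
turnover statistic is designed to expose; and the per-capita estimates
(27.9%, 39.9%, 14.8% of individuals carrying each gene) recover the planted
carriage fractions of 0.28, 0.40 and 0.15 to within sampling error. The
output directory holds, per family: FASTA pools, membership tables, newick
guide trees, count/RPKM/relative-abundance TSVs (rows in guide-tree order),
per-capita series, diversity and cumulative-diversity profiles, Bray–Curtis
pair tables, the environmental regression grid, and a `manifest.json` whose
per-file checksums make reruns verifiably identical.

A thin CLI wrapper with the same stages lives at `inst/cli/genediv.R`
(`run-all`, `simulate`, `cluster`, `diversity`, `stats`).

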