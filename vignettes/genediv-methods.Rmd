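---
title: "Methods: within-gene phylotype diversity from time-series metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-gene phylotype diversity from time-series metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genediv)
```

## The question the package addresses

Microbial communities are thought to buffer ecosystem functions against
environmental change because several taxa can perform the same function and
respond differently to conditions. `genediv` studies this redundancy one
level below the organism: for a single functional gene family (say, a
nitrate reductase), how many distinguishable sequence variants — phylotypes —
carry the function in a community, how evenly are they represented, and how
much does the phylotype profile reshuffle as conditions change through a
season? Families can maintain their total abundance in two contrasting ways:
a *resistant* profile, in which the same phylotypes persist throughout, or a
*resilient* one, in which phylotypes replace each other as conditions shift.
Families with very low within-gene diversity are potential bottlenecks: if
their few carriers fail, no replacement pool exists.

The package implements the full analysis chain — phylotype definition, read
recruitment and normalization, diversity and turnover statistics, and
environmental regressions — together with a synthetic community generator
that plants known structure, so every stage can be validated end to end
against ground truth.

## Phylotype definition

Phylotypes are defined by greedy centroid clustering of protein sequences at
a global-alignment amino-acid identity threshold, 0.90 by default (roughly
the within-genus level of similarity for protein-coding genes). Identity is
computed from a Needleman–Wunsch global alignment under BLOSUM62 scoring
with affine gap costs (open 11, extend 1):

$$\mathrm{identity} = \frac{\#\ \text{identical aligned residue pairs}}
{\#\ \text{alignment columns, gaps included}}$$

Counting gap columns in the denominator makes identity conservative for
length-discordant pairs; dividing by the shorter sequence length instead is
available as `clustering_params(identity_denominator = "shorter")`. Because
co-optimal alignments can differ in column count, each pair is aligned in a
canonical (lexicographic) order so that identity is exactly symmetric.

The greedy pass visits sequences longest-first (ties broken by id), attaches
each sequence to the first existing representative at or above the
threshold (representatives compared in founding order), and otherwise founds
a new phylotype. This is the CD-HIT family of algorithms, made fully
deterministic by the explicit ordering rules; the test suite checks it
against a naive all-pairs reference implementation of the same rule.
The guide tree used to order heatmap rows is UPGMA on `1 - identity`.
UPGMA is deliberately modest: the tree's only job here is a stable,
similarity-respecting row order for display, not phylogenetic inference, so
approximate-ML machinery would add cost without changing any downstream
number.

## Abundance profiling

Reads are recruited to reference coding sequences by exact k-mer seeds
(16 nt, taken at the start, middle and end of the read) followed by
comparison of the full read against the implied ungapped reference window;
the best hit at ≥ 0.95 nucleotide identity wins, with ties broken toward the
lexicographically smallest reference id so counts are reproducible. The
ungapped (band width zero) comparison is exact for the data this package
generates — the simulator introduces substitutions only — and is documented
as a limitation for real indel-bearing reads.

Counts become RPKM (reads per kilobase of gene length per million reads):

$$\mathrm{RPKM} = \frac{c}{(L/1000)\,(N/10^6)}$$

with `c` the read count, `L` the reference length and `N` the per-sample
library size. Two normalizations are derived from RPKM:

* **per-capita gene abundance** — summed family RPKM divided by summed
  RPKM of a universal single-copy marker (an rplB analogue, pooling all
  marker forms). Since every individual carries exactly one marker copy,
  this ratio estimates the fraction of individuals carrying the gene.
* **phylotype relative abundance** — member-sequence RPKM summed into
  phylotypes, each sample column divided by its column total. All-zero
  columns stay zero and are flagged `not_observed`.

Multi-mapping is resolved best-hit (not fractionally) to keep counts
integral; this choice is recorded in the run manifest.

## Diversity and turnover statistics

For each family and sample: richness (number of phylotypes with positive
abundance) and inverse Simpson diversity `1 / sum(p_i^2)`, an
evenness-sensitive index bounded by richness. Cumulative profiles pool RPKM
from each time point with all previous time points and renormalize —
pooling observations rather than averaging proportions, so cumulative
richness is exactly the union of observed phylotypes and is monotone
non-decreasing — and are reported as differences from the initial state.

Temporal turnover is the mean abundance variance: for each phylotype the
unbiased (n − 1) variance of its relative abundance across all time points,
averaged over phylotypes. Time points where a phylotype is unobserved enter
as zeros; consequently appending an all-zero phylotype lowers the mean, and
the estimator choice (n − 1, zeros included) is stated in the manifest
because the statistic's absolute value depends on it. Beta diversity uses
Bray–Curtis dissimilarity `sum|u - v| / sum(u + v)`, and distance-decay
regresses dissimilarity on time lag for all sample pairs — lag in
sample-index units by default and calendar days when dates are supplied,
since either axis convention is defensible and both are emitted.

## Inferential statistics

Welch's t (Welch–Satterthwaite df), Levene's test (F on absolute deviations
from the group mean; `center = "median"` gives Brown–Forsythe),
Mann–Whitney–Wilcoxon, Pearson correlation and simple OLS regression are
implemented from first principles, two-sided throughout. The exact
Mann–Whitney p-value is computed from the full null distribution of U via
the Gaussian-binomial counting recurrence whenever `n1 * n2 <= 400` and
there are no ties (the 6-early-versus-5-late seasonal design always takes
this path); otherwise a tie-corrected, continuity-corrected normal
approximation is used. The suite verifies all five against independent
reference implementations on random inputs, checks exact Mann–Whitney
against brute-force enumeration of all rank arrangements for every group
size up to 8, and calibrates type-I error at the 5% level by null
simulation.

The environmental regression grid fits one OLS per (family metric ×
covariate) cell and annotates p < 0.05 and p < 0.10 cells, reporting raw
p-values (as is conventional for exploratory environmental screens) with a
Benjamini–Hochberg column alongside. For the between-family variability
contrast ("is family A's phylotype profile more volatile than family
B's?"), the package groups the per-phylotype temporal variances of each
family and compares groups with Levene's test. Other groupings are
conceivable (for example per-sample dispersions); this interpretation is
flagged in `family_variability_test()`'s documentation.

## The synthetic community generator

The generator is the package's stand-in for field metagenomes and defines
the study conditions for all validation:

* **Sampling design** — 11 time points at three-week intervals with a
  hydrologic shift after the 6th (6 early, 5 late). Temperature follows a
  rise-then-fall seasonal arc (~9–20 °C); chloride (groundwater proxy)
  steps up (5.5 → 13 mg/L) and organic carbon steps down (0.9 → 0.35 mg/L)
  at the shift; dissolved oxygen stays near 9 mg/L. Gaussian noise scales
  with `noise_scale`.
* **Abundance dynamics** — softmax of Gaussian random walks on
  log-abundance from a Dirichlet initial draw. A single scalar
  (`walk_sigma`, the per-step sd) maps monotonically onto the turnover
  statistic, which is exactly what the regime contrast needs:
  `walk_sigma = 0` gives zero turnover, resistant presets use 0.10–0.25,
  resilient presets 0.80. `dominance_alpha` concentrates the initial
  profile (0.15 plants one dominant phylotype).
* **Family presets** — seven regimes spanning the observed
  diversity/turnover space: high-richness/low-turnover (52 and 51
  phylotypes), lower-richness/high-turnover (31 and 23), a 2-phylotype and
  a 7-phylotype/one-dominant low-richness family, and a 124-phylotype
  universal marker. Carriage fractions (0.28, 0.25, 0.16, 0.40, 0.10,
  0.15; marker 1.0) sit at the midpoints of typical per-capita abundances
  for such families.
* **Sequences** — random founder proteins (60 aa by default) per
  phylotype, variants by point substitution. Bounds (within-phylotype
  identity ≥ 0.95, between ≤ 0.60) are enforced by rejection sampling and
  verified with the clustering aligner itself: founder pairs are checked
  against `0.60 - 2(1 - 0.95)`, which bounds every variant pair by 0.60
  without aligning all O((nv)²) pairs. The margins guarantee that
  clustering at 0.90 recovers the planted partition exactly.
* **Reads** — single-end, uniform start positions, sampling probability
  proportional to abundance × carriage × gene length; the marker is drawn
  at one copy per individual. Substitution errors at 0.005/base; constant
  Q30 qualities. Defaults: 1e5 reads per sample, 100 nt reads. Read depth
  per sample is not a quantity with a canonical field value at this scale,
  so it is configurable; 1e5 gives per-capita estimates with sub-percent
  sampling error.

What the generator does *not* emulate — paired-end inserts, quality
profiles, chimeras, indels, strain microdiversity below the phylotype
threshold, partial gene assembly — bounds what green tests mean: they
demonstrate correctness of the analysis chain on communities with planted
structure, not robustness to every artifact of real sequencing.

## Numerical and design choices

* Identity threshold margins (`between < threshold − 0.03 < within − 0.06`)
  are validated up front; generation fails loudly rather than emitting a
  pool violating its bounds.
* Relative-abundance columns must sum to 1 within 1e-9 (asserted
  throughout); `inverse_simpson` renormalizes only within 1e-6 and errors
  otherwise; the empty profile is defined as 0 with an `empty` flag so
  rectangular series survive missing samples.
* Degenerate inputs are contracts, not crashes: zero-read samples warn and
  stay empty, zero marker signal yields `NA` per-capita with a warning,
  all-zero Bray–Curtis pairs return `NA` with a warning, tied Levene
  deviations return a flagged `NA` statistic.
* All stochastic functions accept an integer seed and are bit-reproducible;
  `run_all()` seeds once and records md5 checksums of every output in its
  manifest, so rerunning a config is verifiably identical.

## Problem sizes

The test suite and the reproduction script keep simulation sizes modest by
choice: the demo pipeline uses three families of 10/6/2 phylotypes with an
8-phylotype marker at 1,000–1,500 reads per sample; the reproduction script
runs all seven presets at 20,000 reads per sample; calibration checks use
1e4 null replicates and 100-fold Monte-Carlo repeats. These sizes give
stable Monte-Carlo margins (binomial error well inside the asserted bounds)
while keeping a full run on one core in the minutes range.

## Known limitations

* Recruitment assumes substitution-only reads (no indel tolerance) and
  uniform read length.
* UPGMA guide trees are for display ordering; branch lengths are not
  interpretable phylogenetically.
* The turnover statistic's absolute value depends on the variance
  convention (documented above); comparisons across studies should match
  conventions before comparing numbers.
* The regression grid reports raw p-values per cell; with ~dozens of cells,
  a handful of nominally significant cells is expected under the null (the
  BH column is provided for that reason).
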