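Package: genediv
Title: Within-Gene Phylotype Diversity Dynamics for Functional Genes in
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-centric analysis of within-gene diversity in time-series
    metagenomes. Clusters functional-gene protein sequences into phylotypes
    by greedy centroid clustering at a global-alignment amino-acid identity
    threshold, recruits reads to reference genes and normalizes counts to
    RPKM and to a single-copy marker (rplB-style) to obtain per-capita gene
    abundances, and computes richness, inverse Simpson, cumulative diversity,
    temporal turnover (mean abundance variance), Bray-Curtis distance decay,
    and environmental regressions. Ships a synthetic-community generator that
    emulates a seasonal hydrologic shift for end-to-end validation, plus
    first-principles implementations of Welch's t, Levene's, and
    Mann-Whitney-Wilcoxon tests and simple linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car
Config/testthat/edition: 3
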