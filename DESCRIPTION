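Package: ventredox
Title: Proteome Carbon Oxidation State and Community Statistics for
    Hydrothermal-Vent Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for redox-oriented analysis of metagenomes and amplicon
    surveys from serpentinization-influenced hydrothermal systems.
    Computes the average carbon oxidation state (Z_C) of predicted
    proteomes from elemental formulas of protein sequences, with
    abundance weighting by the encoding genes and a replicate
    subsampling estimator of per-sample Z_C distributions, compared
    across samples by Welch and Wilcoxon tests.  Provides trimmed mean
    of M-values (TMM) and cumulative-sum-scaling (CSS) normalization of
    count tables, Bray-Curtis distances with ANOSIM, PERMANOVA and
    Mantel permutation tests, KEGG-module completeness scoring with a
    half-missing detection rule, marker-gene and hydrogenase profiling,
    lineage relative-abundance estimation, and a synthetic-data
    generator with analytically known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    edgeR,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
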