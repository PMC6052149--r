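Package: vocdiff
Title: Differential Analysis of Urinary Volatile Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-group differential analysis of untargeted GC-MS
    volatile organic compound (VOC) peak tables: detection filtering and
    total-identified-metabolite (mTIC) normalization, an integrative
    hypothesis test that combines permutation p-values of a Welch t
    statistic, a log2-median-ratio statistic and the Wilcoxon rank-sum
    test via Stouffer's method with a permutation-calibrated combined
    p-value, Storey q-value false discovery rate estimation, CAS registry
    number to KEGG compound annotation with pathway mapping, and a
    companion microarray workflow (Welch differential expression with
    fold-change and abundance filters, hypergeometric Gene Ontology
    enrichment). Seeded synthetic-data generators for both platforms allow
    the whole pipeline to be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    limma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
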