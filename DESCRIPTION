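Package: duplicability
Title: Classification and Comparative Analysis of Whole-Genome and
    Small-Scale Gene Duplicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying gene duplicability in the vertebrate
    lineage. Classifies genes as 2R whole-genome-duplication ohnologs,
    small-scale-duplication (SSD) paralogs, or singletons from paralog
    pair tables and macrosynteny segments, using synteny-block ohnolog
    calling, retroduplication filtering with a microsynteny check, and
    majority-rule consensus across three ohnolog data sets. Provides the
    downstream comparative pipeline: tissue-specificity (tau) and
    duplicate-age feature engineering, Mann-Whitney group comparisons
    with Bonferroni correction, age/type regression models with
    transformation selection, an age-controlled random-forest
    permutation-importance protocol with feature-dependence and
    correlated-feature isolation analyses, and hypergeometric term
    enrichment with cross-class overlap summaries. A synthetic-data
    generator with planted class structure makes every stage testable
    without external genome resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
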