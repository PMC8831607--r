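Package: rvburden
Title: Rare-Variant Gene-Collapsing Burden Analysis for Case-Control Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level collapsing analysis of rare variants in case-control
    whole-exome cohorts. Provides variant- and sample-level quality control,
    per-site case/control coverage harmonization by an exact two-sided binomial
    test, a registry of qualifying-variant models (loss-of-function, damaging
    missense, TraP-rescued splicing, frequency-tiered, recessive, synonymous
    negative control, and a complementary common-LOF model), per-gene carrier
    collapsing with two-tailed Fisher exact tests and Bonferroni genome- and
    study-wide thresholds, genomic-inflation diagnostics with QQ order-statistic
    bands, distinct-carrier-haplotype counting for hotspot versus founder
    evidence, and CpG-deamination transition classification. Includes a
    synthetic-cohort simulator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
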