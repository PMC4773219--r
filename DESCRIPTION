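Package: rarecnv
Title: Rare Copy-Number-Variant Discovery for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for discovering rare copy number variants
    (CNVs) in SNP-array case-control cohorts, modelled on hypertension-related
    left-ventricular-hypertrophy studies. Provides echocardiographic phenotype
    classification (Devereux left-ventricular mass index with sex-specific
    hypertrophy thresholds), per-sample array quality control (call rate,
    LRR/BAF noise, batch-ratio noise, aggregate-CNV-length outliers),
    multi-algorithm consensus merging by reciprocal-overlap single linkage,
    CNV-level filtering (probe support, GC content, centromere/telomere
    proximity, size, sex chromosomes), rarity and novelty assessment against
    reference variant sets, case/control specificity, recurrence detection,
    gene annotation, and burden statistics. A synthetic-data generator
    emulates the full study design - genome scaffold, probe manifest,
    reference sets, phenotyped cohort, planted CNV landscape and three
    imperfect calling algorithms - with a ground-truth ledger for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
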