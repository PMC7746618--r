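Package: kdwgrs
Title: Weighted Genetic Risk Scoring for IVIG Resistance in Kawasaki Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control SNP association scanning, two-stage risk-locus
    selection, weighted genetic risk scores (wGRS) with ln(odds-ratio)
    weights, and a composite bagged-tree classifier combining the wGRS with
    laboratory variables, evaluated by ROC analysis with Youden cutpoints.
    Includes GATK-style variant hard filtering on VCF quality annotations and
    a synthetic case-control cohort generator (planted allelic effects under
    Hardy-Weinberg proportions, group-specific clinical distributions with
    missingness) so the full pipeline is testable without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
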