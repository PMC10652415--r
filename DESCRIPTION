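Package: cnvLongevity
Title: CNV-Gene-Longevity Causality Network Inference for Aging Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers causal CNV-gene-age-of-death networks in aging cohorts
    from copy-number dosage matrices, log2 expression matrices and clinical
    phenotypes. Provides covariate-adjusted linear association scans
    (CNV-longevity and CNV-expression eQTL), disease-severity
    residualization of expression, Spearman gene-longevity screening,
    a from-scratch Causal Inference Test (CIT) with permutation-based
    conditional-independence testing and scenario selection, allele and
    carrier frequency summaries, reciprocal-overlap validation against
    external CNV sets, Kaplan-Meier/log-rank survival by dosage group,
    Fisher's exact gene-set over-representation, Cytoscape network export,
    and a synthetic cohort generator with known mediation ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
biocViews: CopyNumberVariation, GeneExpression, NetworkInference,
    Survival, GraphAndNetwork
RoxygenNote: 7.3.3
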