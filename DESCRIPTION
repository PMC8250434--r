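Package: hmexome
Title: Family-Based Exome Variant Prioritization for High Myopia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease variants from whole-exome sequencing
    of high-myopia families. Implements a four-step filter cascade (consequence,
    synonymous exclusion, population allele-frequency exclusion, per-family
    inheritance-model genotype filtering with de novo exclusion), pedigree
    cosegregation testing under autosomal dominant and recessive models, an
    eleven-category evidence matrix with configurable weights for candidate
    ranking, a minimal ACMG-style evidence labelling (PM2/PP1/PP3), per-family
    clinical summaries of refractive error and axial length, and a gene-drop
    cohort simulator that generates multi-family VCF/PED/annotation fixtures
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
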