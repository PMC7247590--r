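Package: gvburden
Title: Gene-Wise Variant Burden Scoring and Pharmacogenomic Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes gene-wise variant burden (GVB) scores, the per-individual
    geometric mean of normalized in-silico deleteriousness scores over retained
    nonsynonymous coding variants, and aggregates them to drug-level burdens
    over a pharmacokinetic/pharmacodynamic drug-gene relation map. Normalizes
    six variant scoring methods (SIFT, MutationTaster, PolyPhen-2 HDIV/HVAR,
    phyloP, GERP++) to a common scale on which lower means more deleterious,
    builds per-individual gold-standard drug sets from a noncoding
    variant-drug-association catalog with optional OMB ethnicity matching, and
    evaluates burden rankings by rank sensitivity, specificity and AUC with
    population and ATC main-group stratification. Ships a population-structured
    cohort simulator with planted synthetic associations so the whole pipeline
    is testable without external genomic resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
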