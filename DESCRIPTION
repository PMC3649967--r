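Package: essvar
Title: Constraint and De Novo Mutation Enrichment Analysis for Human
    Orthologs of Mouse-Essential Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds essential (EG) and non-lethal (NLG) human gene sets from
    mouse phenotype annotations and an ortholog map, parses effect-annotated
    multi-sample VCFs into typed variant records, computes gene-set constraint
    statistics (length-corrected variant rates, site-frequency-spectrum
    shifts, Fisher 2x2 panels with Woolf confidence intervals, conservation
    and substitution-rate comparisons), accounts per-individual mutational
    load over gene sets and frequency strata, and tests de novo mutation
    enrichment with a gene-based permutation null matched on total exon
    length and GC content, combining studies by inverse-variance fixed-effects
    meta-analysis with Cochran's Q. A synthetic-data module generates every
    pipeline input from explicit distributions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
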