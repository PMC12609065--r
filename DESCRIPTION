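Package: mitoHet
Title: Mitochondrial Heteroplasmy Transmission Analysis and Germline
    Bottleneck Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the germline transmission of mitochondrial
    DNA (mtDNA) heteroplasmy in pedigree cohorts. Provides a circular
    mitochondrial reference model with codon-level functional classification
    under the vertebrate mitochondrial genetic code and synonymous /
    nonsynonymous site counting; readers for per-animal variant-call tables
    and per-sample VCF; the cohort-level variant inclusion filters used in
    mutator-mouse heteroplasmy studies (heteroplasmic-fraction threshold and
    recurrence exclusion); per-animal and per-group statistics (mean
    heteroplasmic fraction, mutational burden, site-normalised N/S ratio,
    pairwise one-dimensional Earth Mover's Distance, kernel-density modes,
    Wilcoxon rank tests, variant coldspots, per-gene variant densities); and
    a Wright-Fisher germline bottleneck simulator with class-dependent
    purifying selection and autophagy-like turnover that generates synthetic
    cohorts with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'filters.R'
    'io.R'
    'stats.R'
    'reference.R'
    'pipeline.R'
    'simulate.R'
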