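Package: barcodeAudit
Title: Auditing DNA Barcode Identification of Border-Intercepted Specimens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing DNA-barcode-based identification of
    specimens intercepted at ports-of-entry against year-stamped,
    access-controlled COI reference libraries. Implements end-gap-free
    pairwise identity with IUPAC ambiguity handling, top-hit retrieval
    against species-level (SLBR-style) and public (PRBD-style) library
    views, a five-category morphology-versus-DNA concordance classifier,
    single-linkage MOTU clustering with per-cluster taxonomic concordance
    audits, reporting arithmetic with a fixed rounding convention, and a
    synthetic-data generator that emulates multi-rank insect taxonomies,
    barcode sequence evolution, calendar-year library growth, and
    morphological identifications truncated at varying ranks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Sequencing, Classification, Clustering
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'barcodeAudit-package.R'
    'binning.R'
    'cli.R'
    'concordance.R'
    'library-io.R'
    'matcher.R'
    'reporting.R'
    'synthetic.R'
    'taxonomy.R'
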