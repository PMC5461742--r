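Package: clonalPair
Title: Clonal Relationships Between Paired Premalignant and Invasive Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired dysplasia and squamous cell carcinoma genomes:
    copy-number event calling from segmented low-coverage profiles, fraction of
    genome altered and cohort frequency statistics, classification of pair
    relationships into four architectural classes, a purity- and copy-number-
    aware somatic mutation filter cascade, the 1/f test for neutral subclonal
    evolution with per-substitution-class mutation-rate estimation, and
    shared-versus-private variant allele frequency comparisons. Includes a
    synthetic cohort generator that emulates neutral subclonal spectra, paired
    lesions with spatially mixed subclones, binomial read sampling and FFPE
    artifacts, so the whole pipeline is testable without patient data.
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
    GenomeInfoDb,
    yaml,
    jsonlite,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
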