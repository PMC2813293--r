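Package: tph2edit
Title: Alternative Splicing and Mutually Exclusive RNA Editing of TPH2 Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clone-based analysis of human tryptophan hydroxylase 2 (TPH2)
    transcript diversity. Builds a constrained surrogate coding-sequence model
    for the two splice isoforms TPH2a and TPH2b, classifies cDNA clones by
    splice isoform with a global affine-gap aligner, discriminates genomic SNPs
    from posttranscriptional RNA edits against per-individual genomic
    sequences, assigns mutually exclusive editing-pattern labels, and
    tabulates stratified editing frequencies. Includes saturation-kinetics
    fitting (Michaelis-Menten and Haldane substrate inhibition, by nonlinear
    least squares and Lineweaver-Burk regression) for comparing enzyme
    variants, Hardy-Weinberg and genotype-association tests, an in-silico NdeI
    restriction digest, and a synthetic-data generator that emulates clone
    libraries, kinetic assays and genotype cohorts with exhaustive truth
    tables for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
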