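Package: oligosurvey
Title: Survey of Abundant Mid-Length Oligonucleotides in Prokaryotic Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of overrepresented 8-14 bp oligonucleotides
    in prokaryotic chromosomes. Counts words strand-specifically, scores them
    against zero-order and second-order Markov null models (one-cell chi-squared
    and Gaussian z statistics), calls over- and underrepresentation with
    copies-per-megabase and chi-squared thresholds, intersects calls across
    taxa, enumerates the 512 homopurine/homopyrimidine octamers, localizes
    occurrences relative to CDS annotation (coding fraction and reading frame),
    and profiles positional distribution in fixed windows. Includes a synthetic
    chromosome generator (i.i.d. background of chosen G+C content, planted word
    enrichment, synthetic CDS annotation) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
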