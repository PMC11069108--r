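Package: mutacc
Title: Mutation-Accumulation Experiment Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for mutation-accumulation (MA) experiments in
    bacteria. Computes mutational target sizes (synonymous/nonsynonymous site
    counting by codon degeneracy, region classification, perfect short-tandem-
    repeat scanning), catalogs and annotates called mutations, estimates
    per-site and per-category mutation rates by Poisson maximum likelihood
    with exact confidence intervals, tests for selection and mutational bias
    against composition-derived nulls, estimates effective population size
    from nucleotide diversity at four-fold degenerate sites, and fits
    phylogenetic generalized least squares regressions of mutation rate on
    effective population size. Includes a synthetic-data generator (annotated
    genomes, simulated MA lines, neutral coalescent alignments) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    rtracklayer,
    vcfR
Config/testthat/edition: 3
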