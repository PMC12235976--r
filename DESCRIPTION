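Package: gbastk
Title: Genotyping by Amplicon Sequencing with SSR and EPIC Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolchain for genotyping-by-amplicon-sequencing (GBAS) in
    non-model diploids: microsatellite (SSR) mining from shotgun reads,
    exon-primed intron-crossing (EPIC) marker discovery from an annotated
    donor genome mapped onto a target genome, constraint-based primer design
    with nearest-neighbor melting temperatures and duplication/contamination
    screens, length- and sequence-aware diploid allele calling from amplicon
    reads with sample/marker/population filters, per-population variability
    statistics (Na, Ne, Ho, He, FIS), Hardy-Weinberg tests, pairwise FST,
    EM estimation of null-allele frequencies, discriminant analysis of
    principal components (DAPC) and Evanno delta-K model selection, plus
    seeded simulators of genotypes, amplicon read sets and toy genome pairs
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
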