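Package: dipstruct
Title: Diploid Single-Cell 3D Genome Reconstruction and Nuclear Architecture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diploid single-cell chromatin contact data of the
    Dip-C family. Implements haplotype imputation of single-cell contacts by
    L^0.5-neighbourhood voting, isolated-contact cleaning, the conditional
    contact-density law, restraint-based 3D genome reconstruction by simulated
    annealing with multi-resolution refinement and structure-based haplotype
    re-imputation, and the downstream nuclear-architecture statistics used to
    contrast pluripotent states: chromosome-territory intermingling,
    compartmentalization score, radial CpG positioning, contacting-CpG single-cell
    compartments with PCA clustering, interchromosomal contact fractions, and
    Lieberman-Aiden A/B compartment calling. A synthetic diploid-nucleus generator
    plants controllable radial CpG architecture ("inside-out" vs "out-inside"),
    chromosome-territory strength and partial phasing, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
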