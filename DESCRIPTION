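Package: sweepload
Title: Genetic Hitchhiking of Deleterious Mutations: Simulation,
    Classification, and Genome-Scale Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how selective sweeps reshape the load of
    deleterious amino-acid polymorphism linked to them. Provides a
    forward-time Wright-Fisher simulator of neutral, deleterious, and
    advantageous mutations with recombination (single sweeps conditional
    on fixation, and recurrent sweeps); frequency-spectrum diversity
    estimators (Watterson's theta, pi, and Fay and Wu's H) by mutation
    class; a per-codon likelihood-ratio classifier of nonsynonymous SNPs
    as deleterious or neutral based on cross-species conservation on a
    fixed phylogeny; recombination-stratified logistic regressions of the
    deleterious-to-neutral SNP ratio with a conservation-density offset;
    hitchhiking-region enrichment contrasts (densities, folds, Fisher and
    z tests, allele-frequency classes, iHS outlier windows, disease-allele
    overlap); a Poisson sliding-window scan for clusters of deleterious
    SNPs; and a synthetic-data generator that emulates every input format
    with known ground truth. All user-facing functions take data frames
    and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    magrittr,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
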