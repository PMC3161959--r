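# Published SNP count tables shipped with the package. These are the
# study's printed tabulations of deleterious (DEL) and neutral (NEU)
# nonsynonymous SNP counts from the 1000 Genomes CEU/CHB+JPT/YRI panels,
# inside and outside hitchhiking regions (regions identified by two or
# more of nine selection scans). They serve as worked-example inputs for
# the enrichment operations.

#' Published deleterious/neutral counts by allele-frequency class
#'
#' Counts of deleterious and neutral nonsynonymous SNPs inside
#' (`del_hh`/`neu_hh`) and outside (`del_out`/`neu_out`) hitchhiking
#' regions, stratified by derived-allele-frequency class (rare
#' `(0, 0.008]`, intermediate `(0.008, 0.059]`, common `(0.059, 1]`).
#'
#' @return A tibble with one row per frequency class.
#' @examples
#' freq_class_counts() %>% enrichment_from_counts()
#' @export
freq_class_counts <- function() {
  read_tsv_checked(
    system.file("extdata", "freq_class_counts.tsv", package = "sweepload",
                mustWork = TRUE),
    c("freq_class", "del_hh", "neu_hh", "del_out", "neu_out")
  )
}

#' Published per-locus counts around known targets of positive selection
#'
#' Deleterious and neutral nonsynonymous SNP counts within ten genes that
#' are putative targets of recent positive selection, and within the
#' regions extending 1 Mb on either side of each gene.
#'
#' @return A tibble: `target`, `del_within`, `neu_within`, `del_flank`,
#'   `neu_flank`.
#' @export
sweep_target_counts <- function() {
  read_tsv_checked(
    system.file("extdata", "sweep_target_counts.tsv", package = "sweepload",
                mustWork = TRUE),
    c("target", "del_within", "neu_within", "del_flank", "neu_flank")
  )
}

#' Published genome-wide non-hitchhiking counts
#'
#' Total deleterious and neutral nonsynonymous SNP counts outside
#' hitchhiking regions (the frequency-class table summed), used as the
#' comparison group for locus-level contrasts.
#'
#' @return A named list with `del` and `neu`.
#' @export
nonhitchhiking_counts <- function() {
  x <- freq_class_counts()
  list(del = sum(x$del_out), neu = sum(x$neu_out))
}
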