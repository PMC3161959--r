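# Readers and writers for the pipeline's plain-text formats. Internal
# coordinates are 0-based half-open everywhere; 1-based coordinates appear
# only at the TSV/VCF boundary (SNP positions are 1-based bp).

#' Read / write BED intervals
#'
#' Standard BED dialect: tab-separated `chrom`, `start`, `end` (0-based
#' half-open), optional extra columns preserved.
#'
#' @param path File path.
#' @param x Tibble with `chrom`, `start`, `end` (+ extras).
#' @return `read_bed()` returns a tibble; `write_bed()` invisibly returns
#'   the path.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^(chrom|#)", first)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, comment.char = "")
  if (!has_header) {
    base <- c("chrom", "start", "end", "name", "score", "strand")
    names(df) <- c(base, paste0("V", seq_len(max(0, ncol(df) - 6))))[seq_len(ncol(df))]
  }
  names(df)[1] <- sub("^#", "", names(df)[1])
  validate_lines(df$start <= df$end, path, "start > end")
  as_tibble(df)
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

validate_lines <- function(ok, path, what) {
  if (!all(ok)) {
    abort(sprintf("%s: malformed line(s) %s (%s)", path,
                  paste(head(which(!ok), 5), collapse = ","), what))
  }
}

read_tsv_checked <- function(path, required) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  as_tibble(df)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genetic map
#'
#' Tab-separated with header: `chrom`, `pos` (bp), `cM` (cumulative
#' centimorgans, non-decreasing within chromosome).
#'
#' @param path File path.
#' @param x Map tibble.
#' @export
read_genetic_map <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "cM"))
  bad <- df %>%
    group_by(.data$chrom) %>%
    summarise(bad = is.unsorted(.data$pos) || is.unsorted(.data$cM), .groups = "drop")
  if (any(bad$bad)) abort(sprintf("%s: genetic map must be sorted and non-decreasing", path))
  df
}

#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(x, path) write_tsv_plain(x, path)

#' Read / write a SNP table
#'
#' Tab-separated with header; required columns `chrom`, `pos` (1-based
#' bp), `ancestral`, `derived`, `derived_freq`, `site_class`
#' (`SYN`/`NONSYN`), `call` (`DEL`/`NEU`/`UNTESTABLE`/`NA`); extra columns
#' (gene, codon_index, gc_class, ...) preserved. Missing frequencies are
#' encoded as `NA`, never silently as zero.
#'
#' @param path File path.
#' @param x SNP tibble.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "ancestral", "derived",
                                 "derived_freq", "site_class", "call"))
  validate_lines(df$pos >= 1, path, "pos < 1")
  df
}

#' @rdname read_snp_table
#' @export
write_snp_table <- function(x, path) write_tsv_plain(x, path)

#' Read / write per-SNP iHS scores
#'
#' Tab-separated with header: `chrom`, `pos`, `ihs` (signed).
#' @param path File path.
#' @param x iHS tibble.
#' @export
read_ihs_table <- function(path) read_tsv_checked(path, c("chrom", "pos", "ihs"))

#' @rdname read_ihs_table
#' @export
write_ihs_table <- function(x, path) write_tsv_plain(x, path)

#' Read / write disease-allele tables
#'
#' Tab-separated with header: `chrom`, `pos`, `category`, optional `freq`
#' and `odds_ratio`.
#' @param path File path.
#' @param x Disease-allele tibble.
#' @export
read_disease_table <- function(path) read_tsv_checked(path, c("chrom", "pos", "category"))

#' @rdname read_disease_table
#' @export
write_disease_table <- function(x, path) write_tsv_plain(x, path)

#' Read a codon alignment from multi-FASTA
#'
#' Reads one gene's codon alignment; sequence lengths must be equal and
#' divisible by three. Returns a character codon matrix (tips x codons)
#' with sequence names as rownames.
#'
#' @param path Multi-FASTA file.
#' @return Character codon matrix.
#' @export
read_codon_alignment <- function(path) {
  rlang::check_installed("Biostrings")
  ss <- Biostrings::readBStringSet(path)
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1) abort(sprintf("%s: unequal sequence lengths", path))
  if (lens[1] %% 3 != 0) abort(sprintf("%s: length not divisible by 3", path))
  seqs <- as.character(ss)
  n_codon <- lens[1] / 3
  m <- do.call(rbind, lapply(seqs, function(s) {
    substring(s, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  }))
  rownames(m) <- names(ss)
  m
}

#' Write a codon alignment to multi-FASTA
#'
#' @param aln Character codon matrix (tips x codons), rownames = taxa.
#' @param path Output file.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste0, collapse = "")
  writeLines(as.vector(rbind(paste0(">", rownames(aln)), seqs)), path)
  invisible(path)
}

#' Read a minimal VCF subset into the SNP-table layout
#'
#' Parses `CHROM`/`POS`/`REF`/`ALT` and the `AF` INFO field of a plain-text
#' VCF (no genotypes needed). VCF positions are 1-based, matching the SNP
#' table's `pos`; the equivalent 0-based half-open interval of a SNP at
#' `pos` is `[pos - 1, pos)`.
#'
#' @param path VCF file path.
#' @return A SNP tibble with `chrom`, `pos`, `ancestral` (REF), `derived`
#'   (ALT), `derived_freq` (AF or `NA`), `site_class = NA`, `call = NA`.
#' @export
read_vcf_snps <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) abort(sprintf("%s: no records", path))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 8
  if (any(bad)) {
    abort(sprintf("%s: malformed line %d (fewer than 8 fields)",
                  path, which(bad)[1] + sum(startsWith(lines, "#"))))
  }
  af <- vapply(parts, function(p) {
    m <- regmatches(p[8], regexec("(?:^|;)AF=([0-9.eE+-]+)", p[8]))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else NA_real_
  }, numeric(1))
  tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    pos = as.numeric(vapply(parts, `[`, character(1), 2)),
    ancestral = vapply(parts, `[`, character(1), 4),
    derived = vapply(parts, `[`, character(1), 5),
    derived_freq = af,
    site_class = NA_character_,
    call = NA_character_
  )
}

#' Write a run manifest
#'
#' Records the command, seed, parameters, and package version of a run so
#' that deterministic stages can be reproduced bit-identically.
#'
#' @param path Output JSON path.
#' @param command Free-text command/stage name.
#' @param seed Seed used.
#' @param params List of parameters (must be JSON-serialisable).
#' @export
write_run_manifest <- function(path, command, seed, params = list()) {
  rlang::check_installed("jsonlite")
  jsonlite::write_json(
    list(command = command, seed = seed, params = params,
         package = "sweepload",
         version = as.character(utils::packageVersion("sweepload"))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
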