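#' Configuration for the synthetic-data generator
#'
#' Describes a small diploid genome with known ground truth from which
#' every pipeline input can be generated: gene/codon annotation, an
#' accessible-CDS mask, a genetic map with hotspots, sweep (hitchhiking)
#' regions with method labels, classified SNPs with class-specific
#' frequency spectra, codon alignments on a tree, iHS score tracks, and
#' disease-allele tables. Every generator is a pure function of
#' (config, seed).
#'
#' Defaults emulate the shape of the real inputs at a reduced scale: two
#' chromosomes, ~3% coding, deleterious spectra skewed rare, sweep regions
#' covering ~10% of the genome in which *neutral* SNPs are thinned by the
#' enrichment factor `f` (deleterious density stays constant), so the true
#' deleterious/neutral fold between regions and background equals `f`.
#'
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param codons_per_gene,cds_fraction Gene size (codons) and coding
#'   fraction of the genome.
#' @param accessible_fraction Fraction of CDS accessible to SNP calling.
#' @param gc_class_probs Probabilities of codon GC classes 0..3.
#' @param conserved_by_gc Conserved-codon probability per GC class.
#' @param n_syn,n_neu,n_del SNP counts by class (synonymous, neutral
#'   nonsynonymous, deleterious nonsynonymous).
#' @param beta_del,beta_neu,beta_syn Beta shape pairs of the
#'   derived-allele-frequency spectra (deleterious skewed rare).
#' @param n_regions,region_width Sweep regions: count and width (bp).
#' @param region_fold Enrichment factor `f` (neutral thinning in regions).
#' @param baseline_cm_mb,n_hotspots,hotspot_cm Genetic map: background
#'   rate, hotspots per chromosome, extra cM per hotspot.
#' @param map_step Genetic-map point spacing (bp).
#' @param centromere_width Width of the central centromere gap (bp).
#' @param n_taxa,n_eutherians Alignment tree: total tips and eutherian
#'   subset size (the human tip is eutherian).
#' @param ds_total Synonymous tree length (substitutions/site).
#' @param aln_conserved_frac,omega_conserved Fraction of codon columns
#'   simulated under the conserved rate ratio, and that ratio.
#' @param ihs_snps_per_mb,ihs_sd_background,ihs_sd_region iHS track: SNP
#'   density and score spread outside/inside sweep regions.
#' @param seed Default seed used by the generators.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_chroms = 2, chrom_length = 25e6,
                         codons_per_gene = 300, cds_fraction = 0.03,
                         accessible_fraction = 0.85,
                         gc_class_probs = c(0.05, 0.35, 0.40, 0.20),
                         conserved_by_gc = c(0.30, 0.45, 0.55, 0.65),
                         n_syn = 12000, n_neu = 9000, n_del = 3600,
                         beta_del = c(0.2, 8), beta_neu = c(0.25, 2),
                         beta_syn = c(0.25, 2),
                         n_regions = 8, region_width = 6e5,
                         region_fold = 1.2,
                         baseline_cm_mb = 1.2, n_hotspots = 10,
                         hotspot_cm = 0.15, map_step = 2e4,
                         centromere_width = 2e6,
                         n_taxa = 16, n_eutherians = 12, ds_total = 12.2,
                         aln_conserved_frac = 0.5, omega_conserved = 0.05,
                         ihs_snps_per_mb = 400, ihs_sd_background = 1,
                         ihs_sd_region = 1.8,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$region_fold > 0, cfg$cds_fraction > 0, cfg$cds_fraction <= 1,
            cfg$accessible_fraction >= 0, cfg$accessible_fraction <= 1,
            all(cfg$conserved_by_gc >= 0), all(cfg$conserved_by_gc <= 1),
            cfg$n_eutherians <= cfg$n_taxa)
  if (cfg$cds_fraction * cfg$chrom_length < 3) abort("chromosome too short for one codon")
  structure(cfg, class = "synth_config")
}

#' Generate the synthetic genome annotation bundle
#'
#' Produces the positional scaffolding used by every other generator:
#' per-codon annotation (with GC class and conserved flag), the
#' accessible-CDS mask, the genetic map, chromosome/centromere info, and
#' sweep regions labelled with the selection-scan methods that "found"
#' them.
#'
#' @param cfg A [synth_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return A list of class `synth_genome`: `codons`, `genes`, `mask`,
#'   `map`, `chrom_info`, `regions`.
#' @export
synth_genome <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  methods9 <- c("iHS", "Rsb", "CLR", "TajimaD1", "TajimaD2", "FayWuH",
                "Fst", "XPEHH", "EHH")
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  gene_len <- cfg$codons_per_gene * 3
  genes <- map(chroms, function(ch) {
    n_genes <- floor(cfg$chrom_length * cfg$cds_fraction / gene_len)
    slot <- cfg$chrom_length / n_genes
    start <- floor((seq_len(n_genes) - 1) * slot +
                     runif(n_genes, 0, slot - gene_len))
    tibble(chrom = ch, gene = sprintf("%s_g%04d", ch, seq_len(n_genes)),
           start = start, end = start + gene_len)
  }) %>% list_rbind()
  cpg <- gene_len / 3
  rep_idx <- rep(seq_len(nrow(genes)), each = cpg)
  codons <- tibble(
    chrom = genes$chrom[rep_idx],
    gene = genes$gene[rep_idx],
    codon_index = rep(seq_len(cpg), times = nrow(genes)),
    start = genes$start[rep_idx] + (rep(seq_len(cpg), times = nrow(genes)) - 1) * 3
  ) %>%
    mutate(
      gc_class = sample(0:3, dplyr::n(), replace = TRUE, prob = cfg$gc_class_probs),
      conserved = runif(dplyr::n()) < cfg$conserved_by_gc[.data$gc_class + 1],
      accessible = runif(dplyr::n()) < cfg$accessible_fraction
    )
  mask <- codons %>%
    filter(.data$accessible) %>%
    transmute(chrom = .data$chrom, start = .data$start, end = .data$start + 3) %>%
    merge_regions()
  map_tbl <- map(chroms, function(ch) {
    pos <- seq(0, cfg$chrom_length, by = cfg$map_step)
    cm <- cfg$baseline_cm_mb * pos / 1e6
    if (cfg$n_hotspots > 0) {
      hs <- sort(runif(cfg$n_hotspots, 0, cfg$chrom_length))
      for (h in hs) cm <- cm + cfg$hotspot_cm * (pos >= h)
    }
    tibble(chrom = ch, pos = pos, cM = cm)
  }) %>% list_rbind()
  chrom_info <- tibble(
    chrom = chroms, length = cfg$chrom_length,
    centro_start = cfg$chrom_length / 2 - cfg$centromere_width / 2,
    centro_end = cfg$chrom_length / 2 + cfg$centromere_width / 2
  )
  if (cfg$n_regions * cfg$region_width > 0.9 * cfg$chrom_length) {
    abort("sweep regions do not fit: n_regions * region_width too large for chrom_length")
  }
  regions <- map(chroms, function(ch) {
    n <- cfg$n_regions
    slot <- cfg$chrom_length / n
    start <- floor((seq_len(n) - 1) * slot +
                     runif(n, 0, slot - cfg$region_width))
    n_tests <- sample(2:9, n, replace = TRUE,
                      prob = 0.6^(2:9))  # most regions found by few tests
    tibble(chrom = ch,
           region = sprintf("%s_r%02d", ch, seq_len(n)),
           start = start, end = start + cfg$region_width,
           n_tests = n_tests,
           methods = vapply(n_tests, function(k) {
             paste(sample(methods9, k), collapse = ",")
           }, character(1)))
  }) %>% list_rbind()
  structure(list(codons = codons, genes = genes, mask = mask, map = map_tbl,
                 chrom_info = chrom_info, regions = regions, seed = seed),
            class = "synth_genome")
}

#' Generate a classified SNP table with known ground truth
#'
#' Places synonymous, neutral nonsynonymous, and deleterious SNPs on
#' accessible codons. Neutral and synonymous SNPs are thinned inside sweep
#' regions by `1/f` (f = `cfg$region_fold`), while deleterious placement is
#' uniform, so the true in/out deleterious-to-neutral fold equals `f`.
#' Derived allele frequencies follow class-specific Beta spectra
#' (deleterious skewed rare). The `call` column carries the classification
#' a perfect classifier would emit; the `truth` tibble is the sidecar that
#' the pipeline itself never reads.
#'
#' @param cfg A [synth_config()].
#' @param genome A [synth_genome()].
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return A list of class `synth_snps`: `snps` (SnpTable layout) and
#'   `truth`.
#' @export
synth_snps <- function(cfg, genome, seed = cfg$seed + 1) {
  set.seed(seed)
  acc <- genome$codons %>% filter(.data$accessible)
  if (nrow(acc) < cfg$n_syn + cfg$n_neu + cfg$n_del) {
    abort("requested SNPs exceed available accessible codons")
  }
  in_region <- points_in_regions(
    acc %>% mutate(pos = .data$start + 2), genome$regions)
  w_del <- rep(1, nrow(acc))
  w_thin <- ifelse(in_region, 1 / cfg$region_fold, 1)
  # weighted sampling without replacement via exponential keys
  # (order statistics of rexp(.)/w), avoiding the quadratic cost of
  # sample(prob = , replace = FALSE) at this scale
  taken <- rep(FALSE, nrow(acc))
  weighted_pick <- function(n, w) {
    w[taken] <- 0  # classes occupy disjoint codons, so positions are unique
    key <- rexp(length(w)) / w
    idx <- order(key)[seq_len(n)]
    taken[idx] <<- TRUE
    idx
  }
  draw <- function(n, w, class, beta, site_class, call) {
    idx <- weighted_pick(n, w)
    bases <- c("A", "C", "G", "T")
    anc_i <- sample.int(4, n, replace = TRUE)
    # derived base: one of the three others, uniformly
    der_i <- (anc_i - 1 + sample.int(3, n, replace = TRUE)) %% 4 + 1
    anc <- bases[anc_i]
    der <- bases[der_i]
    acc[idx, ] %>%
      transmute(chrom = .data$chrom, pos = .data$start + 2,
                gene = .data$gene, codon_index = .data$codon_index,
                gc_class = .data$gc_class,
                ancestral = anc, derived = der,
                derived_freq = pmin(pmax(rbeta(n, beta[1], beta[2]), 1e-4), 0.9999),
                site_class = site_class, call = call,
                true_class = class, in_region = in_region[idx])
  }
  snps <- bind_rows(
    draw(cfg$n_del, w_del, "deleterious", cfg$beta_del, "NONSYN", "DEL"),
    draw(cfg$n_neu, w_thin, "neutral", cfg$beta_neu, "NONSYN", "NEU"),
    draw(cfg$n_syn, w_thin, "synonymous", cfg$beta_syn, "SYN", NA_character_)
  ) %>% arrange(.data$chrom, .data$pos)
  truth <- snps %>% select("chrom", "pos", "true_class", "in_region")
  snps <- snps %>% select(-"true_class", -"in_region")
  structure(list(snps = snps, truth = truth, seed = seed),
            class = "synth_snps")
}

#' Generate codon alignments with known per-site rate ratios
#'
#' Simulates codon columns on a random tree scaled to `cfg$ds_total`
#' synonymous substitutions per site. A fraction `cfg$aln_conserved_frac`
#' of sites evolve at the conserved ratio `cfg$omega_conserved`; the rest
#' at `omega = 1`. Columns are grouped into genes of `cfg$codons_per_gene`
#' codons.
#'
#' @param cfg A [synth_config()].
#' @param n_genes Number of gene alignments.
#' @param seed RNG seed (defaults to `cfg$seed + 2`).
#' @return A list of class `synth_alignments`: `alignments` (named list of
#'   codon matrices), `tree` (dS-scaled, tip `"human"` plus `spN` tips),
#'   `eutherians`, and `truth` (per-gene, per-site omega).
#' @export
synth_alignments <- function(cfg, n_genes = 2, seed = cfg$seed + 2) {
  set.seed(seed)
  tree <- ape::rtree(cfg$n_taxa, tip.label = c("human", sprintf("sp%02d", seq_len(cfg$n_taxa - 1))))
  tree <- scale_tree_ds(tree, cfg$ds_total)
  eutherians <- c("human", sprintf("sp%02d", seq_len(cfg$n_eutherians - 1)))
  S <- n_genes * cfg$codons_per_gene
  omega <- ifelse(runif(S) < cfg$aln_conserved_frac, cfg$omega_conserved, 1)
  cols <- simulate_codon_columns(tree, omega = omega)
  idx <- split(seq_len(S), rep(seq_len(n_genes), each = cfg$codons_per_gene))
  alignments <- imap(idx, function(ii, g) cols[, ii, drop = FALSE])
  names(alignments) <- sprintf("gene%03d", seq_len(n_genes))
  truth <- tibble(
    gene = rep(names(alignments), each = cfg$codons_per_gene),
    codon_index = rep(seq_len(cfg$codons_per_gene), times = n_genes),
    omega = omega
  )
  structure(list(alignments = alignments, tree = tree,
                 eutherians = eutherians, truth = truth, seed = seed),
            class = "synth_alignments")
}

#' Generate iHS score tracks and disease-allele tables
#'
#' iHS scores are drawn from a wider distribution inside sweep regions
#' (`cfg$ihs_sd_region` versus `cfg$ihs_sd_background`), so the fraction
#' of |iHS| > 2 SNPs is elevated there. Disease alleles are placed in
#' categories with configurable in-region placement weights and frequency
#' spectra; a truth manifest records region membership.
#'
#' @param cfg A [synth_config()].
#' @param genome A [synth_genome()].
#' @param categories Tibble describing disease categories: `category`,
#'   `n`, `freq_beta1`, `freq_beta2`, `na_freq_frac` (fraction with
#'   missing frequency), `region_weight` (relative in-region placement),
#'   `has_or` (draw odds ratios?).
#' @param seed RNG seed (defaults to `cfg$seed + 3`).
#' @return A list of class `synth_scores`: `ihs`, `diseases`, `truth`.
#' @export
synth_scores_and_diseases <- function(cfg, genome,
                                      categories = default_disease_categories(),
                                      seed = cfg$seed + 3) {
  set.seed(seed)
  n_ihs <- ceiling(cfg$ihs_snps_per_mb * cfg$chrom_length / 1e6)
  ihs <- map(genome$chrom_info$chrom, function(ch) {
    tibble(chrom = ch,
           pos = sort(sample.int(cfg$chrom_length, n_ihs)))
  }) %>% list_rbind()
  in_region <- points_in_regions(ihs, genome$regions)
  ihs$ihs <- rnorm(nrow(ihs), 0,
                   ifelse(in_region, cfg$ihs_sd_region, cfg$ihs_sd_background))
  genome_bp <- sum(genome$chrom_info$length)
  region_bp <- sum(genome$regions$end - genome$regions$start)
  diseases <- pmap(categories, function(category, n, freq_beta1, freq_beta2,
                                        na_freq_frac, region_weight, has_or) {
    p_in <- region_weight * region_bp /
      (region_weight * region_bp + (genome_bp - region_bp))
    inside <- runif(n) < p_in
    pos <- numeric(n)
    chrom <- character(n)
    if (any(inside)) {
      ridx <- sample.int(nrow(genome$regions), sum(inside), replace = TRUE)
      chrom[inside] <- genome$regions$chrom[ridx]
      pos[inside] <- floor(runif(sum(inside), genome$regions$start[ridx] + 1,
                                 genome$regions$end[ridx]))
    }
    if (any(!inside)) {
      cidx <- sample.int(nrow(genome$chrom_info), sum(!inside), replace = TRUE)
      chrom[!inside] <- genome$chrom_info$chrom[cidx]
      pos[!inside] <- sample.int(cfg$chrom_length, sum(!inside), replace = TRUE)
    }
    freq <- rbeta(n, freq_beta1, freq_beta2)
    freq[runif(n) < na_freq_frac] <- NA_real_
    tibble(category = category, chrom = chrom, pos = pos, freq = freq,
           odds_ratio = if (has_or) rlnorm(n, 0, 0.5) else NA_real_,
           placed_in_region = inside)
  }) %>% list_rbind()
  truth <- diseases %>% select("category", "chrom", "pos", "placed_in_region")
  diseases <- diseases %>% select(-"placed_in_region")
  structure(list(ihs = ihs, diseases = diseases, truth = truth, seed = seed),
            class = "synth_scores")
}

#' Default synthetic disease-allele categories
#'
#' Emulates the shape of curated disease-variant resources: a Mendelian
#' variant catalog (mostly rare, some missing frequencies), its common
#' subset enriched in sweep regions, genome-wide-association risk alleles
#' (common, with odds ratios), and their nonsynonymous subset.
#'
#' @return A tibble consumed by [synth_scores_and_diseases()].
#' @export
default_disease_categories <- function() {
  tibble(
    category = c("mendelian_rare", "mendelian_common", "gwas", "gwas_nonsyn"),
    n = c(800, 250, 600, 80),
    freq_beta1 = c(0.3, 2, 2, 2),
    freq_beta2 = c(8, 4, 3, 3),
    na_freq_frac = c(0.3, 0, 0, 0),
    region_weight = c(0.6, 1.5, 0.9, 1.4),
    has_or = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' Generate the full synthetic input bundle
#'
#' Convenience wrapper running every generator with consecutive seeds
#' derived from `seed`.
#'
#' @param cfg A [synth_config()].
#' @param seed Master seed (defaults to `cfg$seed`).
#' @param n_genes Gene alignments to simulate.
#' @return A list: `genome`, `snps`, `alignments`, `scores`.
#' @export
synth_bundle <- function(cfg, seed = cfg$seed, n_genes = 2) {
  cfg$seed <- seed
  genome <- synth_genome(cfg, seed)
  snps <- synth_snps(cfg, genome, seed + 1)
  alignments <- synth_alignments(cfg, n_genes = n_genes, seed = seed + 2)
  scores <- synth_scores_and_diseases(cfg, genome, seed = seed + 3)
  list(genome = genome, snps = snps, alignments = alignments, scores = scores)
}
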