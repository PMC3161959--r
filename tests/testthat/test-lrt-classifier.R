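test_that("the internal genetic code matches the Biostrings standard code", {
  skip_if_not_installed("Biostrings")
  code <- Biostrings::GENETIC_CODE
  internal <- sweepload:::standard_genetic_code()
  expect_equal(unname(internal[names(code)]), as.character(code))
})

test_that("codon encoding maps gaps and invalid codons to missing", {
  st <- encode_codons(c("ATG", "TAA", "---", "NNN", "atg", NA))
  expect_equal(is.na(st), c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(st[1], st[5])
  expect_equal(attr(st, "n_invalid"), 2)  # stop codon and NNN; gaps excluded
})

test_that("zero-length branches collapse the likelihood to the stationary term", {
  tree <- star_tree(2, total_ds = 12.2)
  tree$edge.length <- rep(1e-9, length(tree$edge.length))
  attr(tree, "ds_total") <- sum(tree$edge.length)
  col <- c(human = "ATG", sp01 = "ATG")
  expect_equal(site_likelihood(col, tree, omega = 1), log(1 / 61), tolerance = 1e-4)
})

test_that("site likelihood equals exhaustive 61-state enumeration on 3-taxon stars", {
  skip_if_not_installed("Biostrings")
  skip_if_not_installed("Matrix")
  tree <- star_tree(3, total_ds = 3)
  bl <- tree$edge.length
  cases <- list(
    list(col = c(human = "ATG", sp01 = "ATG", sp02 = "ATG"), omega = 1),
    list(col = c(human = "ATG", sp01 = "ATA", sp02 = "CTG"), omega = 1),
    list(col = c(human = "AAA", sp01 = "AAG", sp02 = "AAT"), omega = 0.05),
    list(col = c(human = "GGC", sp01 = "GGT", sp02 = "AGC"), omega = 3)
  )
  for (cs in cases) {
    ours <- site_likelihood(cs$col, tree, cs$omega)
    oracle <- oracle_star_likelihood(unname(cs$col), bl, cs$omega)
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("likelihood on a star tree is invariant to tip order", {
  tree <- star_tree(5, total_ds = 6)
  col <- c(human = "ATG", sp01 = "ATA", sp02 = "CTG", sp03 = "ATG", sp04 = "TTG")
  perm <- col[c(3, 1, 5, 2, 4)]
  expect_equal(site_likelihood(col, tree, 1), site_likelihood(perm, tree, 1),
               tolerance = 1e-10)
})

test_that("the LRT statistic is non-negative and the chi-square cutoff is honoured", {
  # 10.83 is the 0.001 quantile boundary of chi-square(1)
  row <- sweepload:::lrt_result_row(-10, -10 + 10.83 / 2, 0.5,
                                    star_tree(3), p_cutoff = 0.001)
  expect_equal(row$lrt_stat, 10.83)
  expect_equal(row$p_value, 0.001, tolerance = 2e-3)
  # a p-value exactly at the cutoff is NOT conserved (strict inequality)
  stat_exact <- qchisq(0.999, df = 1)
  row2 <- sweepload:::lrt_result_row(-10, -10 + stat_exact / 2, 0.5,
                                     star_tree(3), p_cutoff = 0.001)
  expect_false(row2$conserved)
  # null nested in alternative: a worse alternative is clamped, never negative
  row3 <- sweepload:::lrt_result_row(-10, -10.5, 2, star_tree(3), 0.001)
  expect_gte(row3$lrt_stat, 0)
})

test_that("grid and optimizer LRT routes agree", {
  tree <- scale_tree_ds(ape::rtree(10, tip.label = c("human", sprintf("sp%02d", 1:9))),
                        12.2)
  cols <- simulate_codon_columns(tree, omega = c(0.05, 0.3, 1, 1), seed = 31)
  g <- lrt_sites(cols, tree, method = "grid")
  o <- lrt_sites(cols, tree, method = "optimize")
  expect_equal(g$lnl_null, o$lnl_null, tolerance = 1e-8)
  expect_equal(g$lnl_alt, o$lnl_alt, tolerance = 1e-3)
  expect_equal(g$conserved, o$conserved)
})

test_that("deeply conserved columns are called conserved with high power", {
  tree <- star_tree(20, total_ds = 12.2)
  cols <- simulate_codon_columns(tree, omega = 0.01, n_sites = 60, seed = 32)
  res <- lrt_sites(cols, tree)
  expect_gt(mean(res$conserved), 0.9)
})

test_that("adding taxa carrying the conserved residue never weakens the signal", {
  stats <- vapply(c(10, 14, 18), function(k) {
    tree <- star_tree(k, total_ds = 12.2)
    col <- setNames(rep("ATG", k), tree$tip.label)
    lrt_site(col, tree)$lrt_stat
  }, numeric(1))
  expect_true(all(diff(stats) >= -1e-6))
})

test_that("SNP classification applies the three deleterious criteria", {
  tree <- star_tree(14, total_ds = 12.2)
  labels <- tree$tip.label
  eutherians <- labels[1:12]
  conserved_col <- setNames(rep("ATG", 14), labels)
  site <- lrt_site(conserved_col, tree)
  expect_true(site$conserved)

  snp <- list(ancestral_codon = "ATG", derived_codon = "GTG")  # M -> V
  call <- classify_snp(snp, site, conserved_col, eutherians)
  expect_equal(call$call, "deleterious")
  expect_equal(call$n_eutherians, 12)

  # derived residue present in another eutherian: criterion 3 fails
  col2 <- conserved_col
  col2["sp03"] <- "GTG"
  site2 <- lrt_site(col2, tree)
  call2 <- classify_snp(snp, site2, col2, eutherians)
  if (isTRUE(site2$conserved)) expect_equal(call2$call, "neutral")
  expect_false(call2$residue_ok)

  # derived residue present only in a NON-eutherian row: criterion 3 holds
  col3 <- conserved_col
  col3["sp13"] <- "GTG"
  call3 <- classify_snp(snp, lrt_site(col3, tree), col3, eutherians)
  expect_true(call3$residue_ok)

  # non-conserved site: neutral
  call4 <- classify_snp(snp, site %>% dplyr::mutate(p_value = 0.5, omega_hat = 1.2),
                        conserved_col, eutherians)
  expect_equal(call4$call, "neutral")

  # synonymous change is an error
  expect_error(
    classify_snp(list(ancestral_codon = "CTG", derived_codon = "TTG"),
                 site, conserved_col, eutherians),
    "not a nonsynonymous SNP"
  )
})

test_that("columns with fewer than 10 aligned eutherians are untestable", {
  tree <- star_tree(14, total_ds = 12.2)
  labels <- tree$tip.label
  eutherians <- labels[1:12]
  col <- setNames(rep("ATG", 14), labels)
  col[eutherians[4:12]] <- "---"   # 3 eutherians left
  call <- classify_snp(list(ancestral_codon = "ATG", derived_codon = "GTG"),
                       NULL, col, eutherians)
  expect_equal(call$call, "untestable")
  # exactly 9 aligned eutherians is still untestable
  col2 <- setNames(rep("ATG", 14), labels)
  col2[eutherians[10:12]] <- "---"
  call2 <- classify_snp(list(ancestral_codon = "ATG", derived_codon = "GTG"),
                        lrt_site(col2, tree), col2, eutherians)
  expect_equal(call2$n_eutherians, 9)
  expect_equal(call2$call, "untestable")
})

test_that("classify_snps runs the table pipeline deterministically", {
  cfg <- synth_config(n_taxa = 12, n_eutherians = 11, codons_per_gene = 20)
  aln <- synth_alignments(cfg, n_genes = 2, seed = 9)
  snps <- tibble::tibble(
    snp_id = c("s1", "s2", "s3"),
    gene = c("gene001", "gene002", "gene001"),
    codon_index = c(1L, 5L, 999L),
    ancestral_codon = c(aln$alignments$gene001["human", 1],
                        aln$alignments$gene002["human", 5], "ATG")
  )
  # derive a nonsynonymous variant of each ancestral codon
  flip_nonsyn <- function(codon) {
    m <- sweepload:::codon_model()
    aa <- m$aa[match(codon, m$codons)]
    cands <- m$codons[m$aa != aa]
    cands[which(vapply(cands, function(x) {
      sum(strsplit(x, "")[[1]] != strsplit(codon, "")[[1]]) == 1
    }, logical(1)))][1]
  }
  snps$derived_codon <- vapply(snps$ancestral_codon, flip_nonsyn, character(1))
  out1 <- classify_snps(snps, aln$alignments, aln$tree, aln$eutherians)
  out2 <- classify_snps(snps, aln$alignments, aln$tree, aln$eutherians)
  expect_identical(out1, out2)
  expect_equal(out1$call[out1$snp_id == "s3"], "untestable")  # absent column
  expect_true(all(out1$call %in% c("deleterious", "neutral", "untestable")))
})
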