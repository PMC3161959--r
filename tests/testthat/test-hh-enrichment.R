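test_that("published frequency-class counts reproduce the printed folds and ratios", {
  out <- enrichment_from_counts(freq_class_counts())
  expect_equal(round(out$fold, 2), c(1.07, 1.10, 1.09))
  expect_equal(round(out$ratio_hh, 2), c(0.64, 0.45, 0.27))
  expect_equal(round(out$ratio_out, 2), c(0.60, 0.41, 0.25))
})

test_that("one-sided Fisher matches its closed forms and the enumeration oracle", {
  expect_equal(fisher_one_sided(1, 0, 0, 1), 0.5)
  # within-gene table of the sweep-target loci against the pooled
  # non-hitchhiking counts
  nh <- nonhitchhiking_counts()
  expect_equal(round(fisher_one_sided(11, 6, nh$del, nh$neu), 4), 0.0023)
  set.seed(301)
  for (i in 1:25) {
    tot <- sample(4:30, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    expect_equal(fisher_one_sided(a, b, c, d), oracle_fisher_enum(a, b, c, d),
                 tolerance = 1e-12)
    # cross-check against the standard implementation's one-sided test
    ft <- fisher.test(matrix(c(a, c, b, d), 2), alternative = "greater")
    expect_equal(fisher_one_sided(a, b, c, d), ft$p.value, tolerance = 1e-9)
  }
  expect_message(p <- fisher_one_sided(0, 0, 3, 4), "empty")
  expect_equal(p, 1)
})

test_that("identical densities give unit fold and a null z test", {
  out <- enrichment_from_counts(tibble::tibble(del_hh = 50, neu_hh = 100,
                                               del_out = 500, neu_out = 1000))
  expect_equal(out$fold, 1)
  expect_equal(out$z, 0)
  # swapping sides inverts the fold
  sw <- enrichment_from_counts(tibble::tibble(del_hh = 500, neu_hh = 1000,
                                              del_out = 50, neu_out = 100))
  expect_equal(sw$fold, 1 / out$fold)
})

test_that("region-based enrichment partitions all classified SNPs", {
  cfg <- synth_config(n_chroms = 1, chrom_length = 1e7,
                      n_syn = 1500, n_neu = 1500, n_del = 600, n_regions = 4)
  g <- synth_genome(cfg, seed = 11)
  s <- synth_snps(cfg, g, seed = 12)
  e <- enrichment(s$snps, g$regions, g$mask)
  expect_equal(e$del_hh + e$del_out, sum(s$snps$call == "DEL", na.rm = TRUE))
  expect_equal(e$neu_hh + e$neu_out, sum(s$snps$call == "NEU", na.rm = TRUE))
  expect_gt(e$fold, 0)
  expect_error(enrichment(s$snps, g$regions,
                          tibble::tibble(chrom = "chr1", start = 0, end = 10)),
               "zero accessible")
})

test_that("the synthetic enrichment factor is recovered within its CI", {
  cfg <- synth_config(n_chroms = 2, chrom_length = 2e7, region_fold = 1.5,
                      n_syn = 0, n_neu = 20000, n_del = 8000)
  g <- synth_genome(cfg, seed = 13)
  s <- synth_snps(cfg, g, seed = 14)
  e <- enrichment(s$snps, g$regions, g$mask)
  expect_gt(e$fold_hi, 1.5 * 0.97)
  expect_lt(e$fold_lo, 1.5 * 1.03)
  # null configuration: fold CI covers 1
  cfg0 <- synth_config(n_chroms = 1, chrom_length = 2e7, region_fold = 1,
                       n_neu = 10000, n_del = 4000)
  g0 <- synth_genome(cfg0, seed = 15)
  s0 <- synth_snps(cfg0, g0, seed = 16)
  e0 <- enrichment(s0$snps, g0$regions, g0$mask)
  expect_gt(e0$fold_hi, 1)
  expect_lt(e0$fold_lo, 1)
})

test_that("frequency classes are right-closed and partition the SNPs", {
  spec <- freq_class_spec()
  snps <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200, 300, 400),
    call = "DEL",
    derived_freq = c(0.008, 0.0081, 0.059, 0.6)
  )
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 50)
  out <- freq_class_ratios(snps, regions, spec)
  expect_equal(out$del_out, c(1, 2, 1))  # 0.008 rare; 0.0081 & 0.059 intermediate
  expect_message(
    freq_class_ratios(dplyr::mutate(snps, derived_freq = c(0, 1.2, 0.5, NA)),
                      regions, spec),
    "dropped")
})

test_that("10-kb rounding is containment-preserving and never shrinks", {
  r <- round_regions(tibble::tibble(chrom = "chr1", start = 14999, end = 3000001))
  expect_equal(r$start, 10000)
  expect_equal(r$end, 3010000)
  set.seed(302)
  orig <- tibble::tibble(chrom = "chr1",
                         start = sample.int(1e6, 20),
                         end = 0) %>%
    dplyr::mutate(end = start + sample.int(1e5, 20))
  rr <- round_regions(orig)
  expect_true(all(rr$start <= orig$start))
  expect_true(all(rr$end >= orig$end))
  expect_true(all((rr$end - rr$start) >= (orig$end - orig$start)))
})

test_that("SNP-to-region distances match the brute-force oracle", {
  set.seed(303)
  regions <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 3),
                            start = c(1e5, 5e5, 9e5, 2e5, 6e5, 8e5))
  regions$end <- regions$start + 5e4
  snps <- tibble::tibble(chrom = sample(c("chr1", "chr2", "chr3"), 40, TRUE),
                         pos = sample.int(1.2e6, 40), call = "DEL")
  d <- sweepload:::points_region_distance(snps, regions)
  expect_equal(d, oracle_point_region_distance(snps$chrom, snps$pos, regions))
})

test_that("distance bins separate in-region SNPs and band outside SNPs", {
  regions <- tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6)
  snps <- tibble::tibble(
    chrom = "chr1",
    pos = c(1.5e6, 2e6 + 150e3, 2e6 + 420e3, 1e6 - 50e3),
    call = c("DEL", "NEU", "DEL", "NEU")
  )
  db <- distance_bins(snps, regions, width = 2e5)
  expect_true(db$snps$in_region[1])
  expect_equal(db$snps$bin[2], 0)   # 150 kb -> [0, 200 kb)
  expect_equal(db$snps$bin[3], 2)   # 420 kb -> [400, 600 kb)
  expect_equal(db$snps$bin[4], 0)
  expect_equal(db$bins$distance_mb[db$bins$in_region], 0)
  expect_error(distance_bins(snps, regions[0, ]), "non-empty")
})

test_that("iHS windows are scored, excluded, and selected per SNP-count bin", {
  set.seed(304)
  # window with 20 SNPs, 3 beyond the threshold: fraction 0.15
  ihs <- tibble::tibble(chrom = "chr1",
                        pos = seq(1, 2e4, length.out = 20),
                        ihs = c(rep(0, 17), 2.5, -2.5, 3))
  w <- ihs_windows(ihs, cutoff = 0.05, min_bin_windows = 1)
  expect_equal(w$windows$frac, 0.15)
  # 9 SNPs: excluded
  w9 <- suppressWarnings(
    ihs_windows(ihs[1:9, ], cutoff = 0.05, min_bin_windows = 1))
  expect_equal(nrow(w9$windows), 0)
  # per-bin top-5% selection with elevated scores inside true regions
  cfg <- synth_config(n_chroms = 2, chrom_length = 2e7, ihs_sd_region = 2.2)
  g <- synth_genome(cfg, seed = 17)
  sc <- synth_scores_and_diseases(cfg, g, seed = 18)
  scan <- ihs_windows(sc$ihs, cutoff = 0.05, min_bin_windows = 20)
  sel <- scan$windows %>% dplyr::filter(selected)
  hit <- sweepload:::points_in_regions(
    sel %>% dplyr::mutate(pos = (start + end) / 2), g$regions)
  # permutation null for the overlap fraction
  all_w <- scan$windows
  obs <- mean(hit)
  null <- vapply(1:200, function(i) {
    idx <- sample.int(nrow(all_w), nrow(sel))
    mean(sweepload:::points_in_regions(
      all_w[idx, ] %>% dplyr::mutate(pos = (start + end) / 2), g$regions))
  }, numeric(1))
  expect_lt((1 + sum(null >= obs)) / 201, 0.01)
})

test_that("disease-allele overlap handles missing frequencies and null layouts", {
  regions <- tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6)
  alleles <- tibble::tibble(
    chrom = "chr1",
    pos = c(1.5e6, 1.6e6, 3e6, 4e6, 5e6),
    category = "omim",
    freq = c(0.2, NA, 0.3, NA, 0.01)
  )
  # missing frequency is treated as zero, hence rare under a 5% cutoff
  ov <- disease_overlap(alleles, regions, split_rare_common = "omim")
  expect_setequal(ov$categories$category, c("omim_rare", "omim_common"))
  expect_equal(ov$categories$n_hh[ov$categories$category == "omim_rare"], 1)
  # everything outside the regions: all ratios zero
  far <- alleles %>% dplyr::mutate(pos = pos + 1e7)
  ov2 <- disease_overlap(far, regions)
  expect_equal(ov2$categories$ratio, 0)
  # identical frequency distributions in and out: rank-sum p well above 0.5
  set.seed(305)
  fr <- rep(c(0.1, 0.2, 0.3, 0.4), 25)
  al3 <- tibble::tibble(
    chrom = "chr1",
    pos = c(seq(1.0e6 + 1, 2e6, length.out = 50), seq(3e6, 4e6, length.out = 50)),
    category = "omim", freq = c(fr[1:50], fr[1:50])
  )
  ov3 <- disease_overlap(al3, regions)
  expect_gt(ov3$freq_test$p_value, 0.5)
  # odds-ratio contrast appears when odds ratios are present
  al4 <- al3 %>% dplyr::mutate(odds_ratio = rep(c(1, 3), 50))
  ov4 <- disease_overlap(al4, regions)
  expect_false(is.null(ov4$or_test))
  expect_equal(ov4$or_test$prop_hh, ov4$or_test$prop_out)
})
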