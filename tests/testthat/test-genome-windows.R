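test_that("window recombination rate follows the most-distant-points rule", {
  # points at 0 and 400 kb with 0.4 cM between them: 1 cM/Mb
  w <- window_rec_rate(tibble::tibble(pos = c(0, 4e5), cM = c(0, 0.4)))
  expect_equal(w$rec_rate, 1.0)
  expect_false(w$excluded)

  # most distant pair only 300 kb apart: excluded with a recorded reason
  w2 <- window_rec_rate(tibble::tibble(pos = c(0, 3e5), cM = c(0, 0.4)))
  expect_true(w2$excluded)
  expect_match(w2$reason, "360000")

  # flat map over 399 kb: rate 0, retained
  w3 <- window_rec_rate(tibble::tibble(pos = c(0, 399e3), cM = c(0.7, 0.7)))
  expect_equal(w3$rec_rate, 0)
  expect_false(w3$excluded)

  expect_error(window_rec_rate(tibble::tibble(pos = c(0, 4e5), cM = c(1, 0.5))),
               "non-decreasing")
})

test_that("window exclusions cover chromosome ends, centromeres, and missing CDS", {
  cfg <- synth_config(n_chroms = 1, chrom_length = 2e7, n_hotspots = 0)
  g <- synth_genome(cfg, seed = 2)
  w <- rec_rate_windows(g$map, g$chrom_info, g$mask, end_buffer = 2e6)
  expect_true(all(w$excluded[w$start < 2e6]))
  expect_true(all(w$excluded[w$end > 2e7 - 2e6]))
  cen <- g$chrom_info
  mid <- w$start < cen$centro_end + 2e6 & w$end > cen$centro_start - 2e6
  expect_true(all(w$excluded[mid]))
  kept <- w[!w$excluded, ]
  # hotspot-free profile: every retained window sits at the baseline rate
  expect_true(all(abs(kept$rec_rate - cfg$baseline_cm_mb) < 0.01 * cfg$baseline_cm_mb))
})

test_that("recombination bins are equal-sized within one window", {
  cfg <- synth_config(n_chroms = 2, chrom_length = 2e7)
  g <- synth_genome(cfg, seed = 3)
  b <- rec_bins(rec_rate_windows(g$map, g$chrom_info, g$mask, end_buffer = 2e6))
  sizes <- table(b$bin)
  expect_equal(length(sizes), 10)
  expect_lte(max(sizes) - min(sizes), 1)
  # bins ordered by recombination rate
  means <- tapply(b$rec_rate, b$bin, mean)
  expect_true(all(diff(means) >= 0))
})

test_that("the conservation offset reduces to its closed forms", {
  base <- tidyr::crossing(bin = 1:5, gc_class = 0:1) %>%
    dplyr::mutate(n_codons = 1000, del = 30, neu = 70)
  # fcon constant across bins: offset equals the class deleterious fraction
  cells <- base %>% dplyr::mutate(n_conserved = ifelse(gc_class == 0, 400, 600))
  off <- conservation_offset(cells)
  expect_equal(unique(off$s_off), 0.3, tolerance = 1e-12)

  # fdel_j = 0: clipped to eps
  cells2 <- cells %>% dplyr::mutate(del = 0)
  off2 <- conservation_offset(cells2)
  expect_equal(unique(off2$s_off), 1e-6)

  # fcon_ij = 2 * mean, fdel = 0.3 -> 0.6
  cells3 <- tibble::tibble(bin = 1:2, gc_class = 2, n_codons = 100,
                           n_conserved = c(20, 40), del = 3, neu = 7)
  off3 <- conservation_offset(cells3)
  expect_equal(off3$s_off[off3$n_conserved == 40], 0.3 * (0.4 / 0.3))
})

test_that("GLM fits match the Newton likelihood oracle to 1e-6", {
  set.seed(201)
  cells <- tidyr::crossing(bin = 1:10, gc_class = 0:3) %>%
    dplyr::mutate(
      r_bin = rep(seq(0.2, 3, length.out = 10), each = 4),
      s_off = plogis(rnorm(40, -0.8, 0.3)),
      n = 500 + rpois(40, 200),
      del = rbinom(40, n, plogis(qlogis(s_off) + 0.4 - 0.12 * r_bin)),
      neu = n - del,
      n_codons = n, n_conserved = del, missing_cell = FALSE
    )
  fit <- fit_recombination_model(cells)
  X <- cbind(1, cells$r_bin)
  beta_oracle <- oracle_binom_newton(X, cells$del, cells$neu,
                                     offset = qlogis(cells$s_off))
  expect_equal(unname(coef(fit$fit)), beta_oracle, tolerance = 1e-6)

  cells_h <- cells %>% dplyr::mutate(h = rep(c(0, 1), 20))
  fith <- fit_hitchhiking_model(cells_h)
  Xh <- cbind(1, cells_h$r_bin, cells_h$h)
  expect_equal(unname(coef(fith$fit)),
               oracle_binom_newton(Xh, cells_h$del, cells_h$neu,
                                   offset = qlogis(cells_h$s_off)),
               tolerance = 1e-6)

  bins <- tibble::tibble(distance_mb = seq(0.1, 4, by = 0.2),
                         del = rbinom(20, 400, plogis(-0.5 - 0.2 * distance_mb)))
  bins$neu <- 400 - bins$del
  fd <- fit_distance_model(bins)
  expect_equal(unname(coef(fd$fit)),
               oracle_binom_newton(cbind(1, bins$distance_mb), bins$del, bins$neu),
               tolerance = 1e-6)
})

test_that("a constant 0.5 offset reduces to the ordinary logistic fit", {
  set.seed(202)
  cells <- tibble::tibble(
    bin = 1:10, gc_class = 1, r_bin = seq(0.5, 3, length.out = 10),
    s_off = 0.5, n = 1000,
    del = rbinom(10, 1000, plogis(-0.3 - 0.1 * r_bin)),
    n_codons = 1, n_conserved = 1, missing_cell = FALSE
  ) %>% dplyr::mutate(neu = n - del)
  fit <- fit_recombination_model(cells)
  plain <- glm(cbind(del, neu) ~ r_bin, family = binomial(), data = cells)
  expect_equal(coef(fit$fit), coef(plain), tolerance = 1e-9)
})

test_that("flat cells give a null slope and degenerate designs error", {
  cells <- tidyr::crossing(bin = 1:10, gc_class = 1) %>%
    dplyr::mutate(r_bin = bin / 2, s_off = 0.5, del = 300, neu = 700,
                  n_codons = 1, n_conserved = 1, missing_cell = FALSE)
  fit <- fit_recombination_model(cells)
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "r_bin"]), 1e-8)
  expect_gt(td$p_value[td$term == "r_bin"], 0.99)
  expect_error(fit_hitchhiking_model(cells %>% dplyr::mutate(h = 0)),
               "degenerate")
  expect_error(fit_distance_model(tibble::tibble(distance_mb = 1, del = 1, neu = 1)),
               ">= 2")
})

test_that("permuting the hitchhiking label centres its coefficient on zero", {
  set.seed(203)
  cells <- tidyr::crossing(bin = 1:10, gc_class = 0:1, h = c(0, 1)) %>%
    dplyr::mutate(r_bin = bin / 3, s_off = 0.4, n = 800,
                  del = rbinom(40, n, plogis(qlogis(s_off) + 0.2 - 0.05 * r_bin)),
                  neu = n - del, n_codons = 1, n_conserved = 1,
                  missing_cell = FALSE)
  b2 <- vapply(1:30, function(i) {
    cells$h <- sample(cells$h)
    if (length(unique(cells$h)) < 2) return(NA_real_)
    coef(fit_hitchhiking_model(cells)$fit)[["h"]]
  }, numeric(1))
  b2 <- b2[!is.na(b2)]
  expect_lt(abs(mean(b2)), 3 * sd(b2) / sqrt(length(b2)) + 0.02)
})

test_that("the biased-gene-conversion filter removes the right SNPs", {
  snps <- tibble::tibble(
    ancestral = c("A", "G", "T", "C", "N", "G"),
    derived = c("G", "A", "C", "T", "A", "T"),
    gc_class = c(2, 2, 2, 2, 2, 0)
  )
  out <- bgc_filter(snps)
  ex <- attr(out, "exclusions")
  # A->G and T->C are the AT-to-GC direction; G->A and C->T are retained
  expect_equal(nrow(out), 2)
  expect_true(all(out$ancestral %in% c("G", "C")))
  expect_equal(unname(ex["at_gc"]), 2)       # A->G and T->C
  expect_equal(unname(ex["unknown_ancestral"]), 1)
  expect_equal(unname(ex["gc0"]), 1)
})

test_that("hitchhiking window labels follow the overlap rules", {
  windows <- tibble::tibble(chrom = "chr1",
                            start = c(0, 4e5, 8e5, 12e5),
                            end = c(4e5, 8e5, 12e5, 16e5))
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(1e5, 9e5), end = c(2e5, 10e5),
                            n_tests = c(5, 2))
  lab <- label_hitchhiking_windows(windows, regions, min_tests = 3)
  expect_equal(lab$h, c(1, 0, NA, 0))
})

test_that("cell aggregation partitions SNPs and codons by bin and GC class", {
  cfg <- synth_config(n_chroms = 1, chrom_length = 2e7,
                      n_syn = 2000, n_neu = 2000, n_del = 800)
  g <- synth_genome(cfg, seed = 5)
  s <- synth_snps(cfg, g, seed = 6)
  b <- rec_bins(rec_rate_windows(g$map, g$chrom_info, g$mask, end_buffer = 2e6))
  cells <- gc_conservation_cells(b, s$snps, g$codons)
  # codon cells partition the codons lying inside retained windows
  in_win <- sum(vapply(seq_len(nrow(b)), function(i) {
    sum(g$codons$chrom == b$chrom[i] & g$codons$start >= b$start[i] &
          g$codons$start < b$end[i])
  }, numeric(1)))
  expect_equal(sum(cells$n_codons), in_win)
  expect_true(all(cells$n_conserved <= cells$n_codons))
  off <- conservation_offset(cells)
  expect_true(all(off$s_off > 0 & off$s_off < 1))
})
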