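#' One-sided Fisher's exact test for a 2x2 enrichment table
#'
#' Upper-tail hypergeometric probability of observing at least `a`
#' deleterious SNPs in the first group, given the table margins — the
#' direction that tests enrichment of deleterious SNPs in hitchhiking
#' regions. Table layout: rows = groups (in / out), columns = (deleterious,
#' neutral): `[a b; c d]`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The one-sided p-value.
#' @examples
#' fisher_one_sided(1, 0, 0, 1)  # 0.5: two equiprobable tables
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) {
    inform("empty table margin; one-sided Fisher p set to 1 by convention")
    return(1)
  }
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) return(list(z = NA_real_, p = NA_real_))
  p <- (x1 + x2) / (n1 + n2)
  if (p <= 0 || p >= 1) return(list(z = 0, p = 1))  # identical degenerate proportions
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

enrichment_row <- function(del_hh, neu_hh, del_out, neu_out,
                           kb_hh = NA_real_, kb_out = NA_real_,
                           conf_level = 0.95) {
  ratio_hh <- ifelse(neu_hh > 0, del_hh / neu_hh, NA_real_)
  ratio_out <- ifelse(neu_out > 0, del_out / neu_out, NA_real_)
  fold <- ratio_hh / ratio_out
  # fold is an odds ratio; normal CI on its log
  if (all(c(del_hh, neu_hh, del_out, neu_out) > 0)) {
    se <- sqrt(1 / del_hh + 1 / neu_hh + 1 / del_out + 1 / neu_out)
    zq <- qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(fold) + c(-1, 1) * zq * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  zt <- two_proportion_z(del_hh, del_hh + neu_hh, del_out, del_out + neu_out)
  tibble(
    del_hh = del_hh, neu_hh = neu_hh, del_out = del_out, neu_out = neu_out,
    del_density_hh = del_hh / kb_hh, neu_density_hh = neu_hh / kb_hh,
    del_density_out = del_out / kb_out, neu_density_out = neu_out / kb_out,
    ratio_hh = ratio_hh, ratio_out = ratio_out, fold = fold,
    fold_lo = ci[1], fold_hi = ci[2], conf_level = conf_level,
    z = zt$z, p_z = zt$p,
    p_fisher = fisher_one_sided(del_hh, neu_hh, del_out, neu_out)
  )
}

#' Deleterious-vs-neutral enrichment inside hitchhiking regions
#'
#' Partitions classified SNPs by region overlap and contrasts the
#' deleterious-to-neutral ratio inside versus outside: densities per kb of
#' accessible CDS, ratios, the fold change (a ratio of odds), a
#' log-odds-ratio confidence interval, a two-proportion z-test, and the
#' one-sided Fisher's exact test.
#'
#' @param snps Tibble with `chrom`, `pos` (1-based bp), and `call`
#'   (`"DEL"` / `"NEU"`; other calls are ignored).
#' @param regions Hitchhiking region tibble (`chrom`, `start`, `end`).
#' @param mask Accessible-CDS mask tibble; required for densities. If the
#'   accessible length is zero on either side the contrast is an error.
#' @param conf_level Confidence level of the fold CI (default 0.95).
#' @return A one-row tibble of class `enrichment_result`.
#' @export
enrichment <- function(snps, regions, mask, conf_level = 0.95) {
  snps <- snps %>% filter(.data$call %in% c("DEL", "NEU"))
  inside <- points_in_regions(snps, regions)
  kb <- mask_split_lengths(mask, regions) / 1000
  if (any(kb <= 0)) abort("zero accessible CDS inside or outside regions")
  out <- enrichment_row(
    del_hh = sum(inside & snps$call == "DEL"),
    neu_hh = sum(inside & snps$call == "NEU"),
    del_out = sum(!inside & snps$call == "DEL"),
    neu_out = sum(!inside & snps$call == "NEU"),
    kb_hh = kb[["inside"]], kb_out = kb[["outside"]],
    conf_level = conf_level
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Frequency classes for enrichment contrasts
#'
#' Derived-allele-frequency classes partitioning `(0, 1]`, right-closed:
#' rare `(0, 0.008]`, intermediate `(0.008, 0.059]`, common `(0.059, 1]`.
#' `disease_cutoff` is the separate rare/common boundary used for disease
#' alleles.
#'
#' @param breaks Increasing break points starting at 0 and ending at 1.
#' @param labels Class labels (one fewer than breaks).
#' @param disease_cutoff Allele-frequency cutoff separating rare from
#'   common disease alleles (default 5%).
#' @return A `freq_class_spec` list.
#' @export
freq_class_spec <- function(breaks = c(0, 0.008, 0.059, 1),
                            labels = c("rare", "intermediate", "common"),
                            disease_cutoff = 0.05) {
  stopifnot(length(labels) == length(breaks) - 1, !is.unsorted(breaks),
            breaks[1] == 0, breaks[length(breaks)] == 1)
  structure(list(breaks = breaks, labels = labels,
                 disease_cutoff = disease_cutoff),
            class = "freq_class_spec")
}

#' Enrichment contrasts by allele-frequency class
#'
#' Splits classified SNPs into derived-allele-frequency classes
#' (right-closed intervals; a frequency exactly at a boundary falls in the
#' lower class) and computes the in/out-of-region enrichment table per
#' class. Frequencies outside `(0, 1]` are dropped with a count.
#'
#' @param snps Tibble with `chrom`, `pos`, `call`, and `derived_freq`.
#' @param regions Region tibble.
#' @param spec A [freq_class_spec()].
#' @param conf_level Fold CI level.
#' @return A tibble with one `enrichment_row` per frequency class, class
#'   `freq_class_result`.
#' @export
freq_class_ratios <- function(snps, regions, spec = freq_class_spec(),
                              conf_level = 0.95) {
  snps <- snps %>% filter(.data$call %in% c("DEL", "NEU"))
  bad <- is.na(snps$derived_freq) | snps$derived_freq <= 0 | snps$derived_freq > 1
  if (any(bad)) {
    inform(sprintf("%d SNPs with frequency outside (0, 1] dropped", sum(bad)))
    snps <- snps[!bad, , drop = FALSE]
  }
  snps$freq_class <- cut(snps$derived_freq, breaks = spec$breaks,
                         labels = spec$labels, right = TRUE)
  inside <- points_in_regions(snps, regions)
  out <- map(spec$labels, function(cl) {
    sel <- snps$freq_class == cl
    enrichment_row(
      del_hh = sum(sel & inside & snps$call == "DEL"),
      neu_hh = sum(sel & inside & snps$call == "NEU"),
      del_out = sum(sel & !inside & snps$call == "DEL"),
      neu_out = sum(sel & !inside & snps$call == "NEU"),
      conf_level = conf_level
    ) %>% mutate(freq_class = cl, .before = 1)
  }) %>% list_rbind()
  class(out) <- c("freq_class_result", class(out))
  out
}

#' Enrichment table from pre-tabulated 2x2 counts
#'
#' Convenience wrapper for published or externally tabulated counts: one
#' row per stratum with columns `del_hh`, `neu_hh`, `del_out`, `neu_out`.
#'
#' @param counts Tibble of counts (extra columns are carried through).
#' @param conf_level Fold CI level.
#' @return Tibble of enrichment rows, class `enrichment_result`.
#' @export
enrichment_from_counts <- function(counts, conf_level = 0.95) {
  extra <- setdiff(names(counts), c("del_hh", "neu_hh", "del_out", "neu_out"))
  rows <- pmap(counts[c("del_hh", "neu_hh", "del_out", "neu_out")],
               enrichment_row, conf_level = conf_level) %>% list_rbind()
  out <- bind_cols(counts[extra], rows)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Score iHS outlier windows and build hitchhiking regions
#'
#' For each non-overlapping window the signal of recent positive selection
#' is the fraction of SNPs with |iHS| above `abs_threshold`. Windows are
#' grouped into bins by SNP count (width `bin_width`, first bin starting at
#' `min_snps`) and an empirical top-`cutoff` selection is applied within
#' each bin, so that SNP-density differences do not drive the outlier
#' call. Windows with fewer than `min_snps` SNPs are excluded, as are bins
#' with fewer than `min_bin_windows` windows (`min_bin_windows_strict` at
#' cutoffs of 0.25% or less).
#'
#' @param ihs Tibble with `chrom`, `pos`, `ihs` (signed scores).
#' @param cutoff Empirical tail fraction selected per bin (default 0.05).
#' @param window_size Window width in bp (default 100 kb).
#' @param abs_threshold |iHS| threshold counting as a selected SNP
#'   (default 2).
#' @param bin_width SNP-count bin width (default 25).
#' @param min_snps Minimum SNPs per scored window (default 10).
#' @param min_bin_windows,min_bin_windows_strict Minimum windows per bin
#'   (100; 400 at cutoffs <= 0.25%).
#' @return A list of class `ihs_scan`: `windows` (scored windows with
#'   `selected` flag) and `regions` (merged selected windows).
#' @export
ihs_windows <- function(ihs, cutoff = 0.05, window_size = 1e5,
                        abs_threshold = 2, bin_width = 25, min_snps = 10,
                        min_bin_windows = 100, min_bin_windows_strict = 400) {
  min_bin <- if (cutoff <= 0.0025) min_bin_windows_strict else min_bin_windows
  w <- ihs %>%
    mutate(win = floor((.data$pos - 1) / window_size)) %>%
    group_by(.data$chrom, .data$win) %>%
    summarise(n_snps = dplyr::n(),
              frac = mean(abs(.data$ihs) > abs_threshold),
              .groups = "drop") %>%
    mutate(start = .data$win * window_size, end = .data$start + window_size) %>%
    filter(.data$n_snps >= min_snps) %>%
    mutate(snp_bin = floor(.data$n_snps / bin_width))
  w <- w %>%
    group_by(.data$snp_bin) %>%
    mutate(bin_n = dplyr::n()) %>%
    ungroup() %>%
    filter(.data$bin_n >= min_bin)
  if (nrow(w) == 0) {
    warn("no window bins survive the exclusion rules; empty region set")
    return(structure(list(windows = w, regions = tibble(chrom = character(), start = numeric(), end = numeric())),
                     class = "ihs_scan"))
  }
  w <- w %>%
    group_by(.data$snp_bin) %>%
    mutate(selected = {
      k <- max(1L, floor(cutoff * dplyr::n()))
      thr <- sort(.data$frac, decreasing = TRUE)[k]
      .data$frac >= thr & .data$frac > 0
    }) %>%
    ungroup()
  regions <- merge_regions(w %>% filter(.data$selected) %>%
                             select("chrom", "start", "end"))
  structure(list(windows = w, regions = regions), class = "ihs_scan")
}

#' Distance of SNPs to the nearest hitchhiking region, binned
#'
#' Assigns each classified SNP its distance to the nearest region edge
#' (0 inside a region); SNPs outside regions are grouped into
#' non-overlapping distance bands of `width` bp, and per-band deleterious /
#' neutral counts are returned for [fit_distance_model()]. SNPs inside
#' regions form the separate `in_region` bin.
#'
#' @param snps Tibble with `chrom`, `pos`, `call`.
#' @param regions Region tibble (must be non-empty).
#' @param width Distance band width in bp (default 200 kb).
#' @return A list: `snps` (with `distance` and `bin`), `bins` (per-band
#'   `del`, `neu`, `distance_mb` at the band midpoint, plus the
#'   `in_region` row flagged).
#' @export
distance_bins <- function(snps, regions, width = 2e5) {
  if (nrow(regions) == 0) abort("regions must be non-empty")
  snps <- snps %>% filter(.data$call %in% c("DEL", "NEU"))
  d <- points_region_distance(snps, regions)
  snps <- snps %>%
    mutate(distance = d,
           in_region = !is.na(d) & d == 0,
           bin = ifelse(.data$in_region, NA_integer_, floor(d / width)))
  bins <- snps %>%
    filter(!is.na(.data$distance)) %>%
    group_by(in_region = .data$in_region, bin = .data$bin) %>%
    summarise(del = sum(.data$call == "DEL"),
              neu = sum(.data$call == "NEU"), .groups = "drop") %>%
    mutate(distance_mb = ifelse(.data$in_region, 0, (.data$bin + 0.5) * width / 1e6)) %>%
    arrange(.data$in_region, .data$bin)
  list(snps = snps, bins = bins)
}

#' Disease-allele overlap with hitchhiking regions
#'
#' Per-category hitchhiking : non-hitchhiking count ratios for
#' disease-associated alleles, with the supporting tests: pairwise
#' one-sided Fisher contrasts between categories, a rank-sum comparison of
#' allele frequencies inside versus outside regions, and (when odds ratios
#' are present) the proportion of risk alleles with odds ratio above
#' `or_threshold` in versus out. Alleles lacking a frequency are treated
#' as frequency zero (hence rare under `freq_cutoff`).
#'
#' @param alleles Tibble with `chrom`, `pos`, `category`, optional `freq`
#'   and `odds_ratio`.
#' @param regions Region tibble.
#' @param freq_cutoff Rare/common cutoff for the `split_rare_common`
#'   categories (default 0.05).
#' @param split_rare_common Categories to split into rare/common
#'   subcategories by `freq_cutoff`.
#' @param or_threshold Odds-ratio threshold (default 2).
#' @param bonferroni Apply a Bonferroni correction to the pairwise Fisher
#'   p-values (off by default, mirroring per-comparison reporting).
#' @return A list of class `disease_overlap`: `categories` (counts and
#'   ratios), `pairwise` (Fisher tests), `freq_test` (rank-sum), and
#'   `or_test` (high-odds-ratio proportion contrast, or `NULL`).
#' @export
disease_overlap <- function(alleles, regions, freq_cutoff = 0.05,
                            split_rare_common = character(),
                            or_threshold = 2, bonferroni = FALSE) {
  alleles <- alleles %>%
    mutate(freq = if ("freq" %in% names(alleles)) coalesce(.data$freq, 0) else 0)
  if (length(split_rare_common) > 0) {
    alleles <- alleles %>%
      mutate(category = ifelse(
        .data$category %in% split_rare_common,
        paste0(.data$category, ifelse(.data$freq > freq_cutoff, "_common", "_rare")),
        .data$category))
  }
  alleles$in_region <- points_in_regions(alleles, regions)
  categories <- alleles %>%
    group_by(.data$category) %>%
    summarise(n_hh = sum(.data$in_region), n_out = sum(!.data$in_region),
              .groups = "drop") %>%
    filter(.data$n_hh + .data$n_out > 0) %>%
    mutate(ratio = ifelse(.data$n_out > 0, .data$n_hh / .data$n_out, NA_real_))
  cats <- categories$category
  pairwise <- NULL
  if (length(cats) >= 2) {
    pairs <- utils::combn(cats, 2, simplify = FALSE)
    pairwise <- map(pairs, function(pr) {
      a <- categories %>% filter(.data$category == pr[1])
      b <- categories %>% filter(.data$category == pr[2])
      tibble(category_a = pr[1], category_b = pr[2],
             p_fisher = fisher_one_sided(a$n_hh, a$n_out, b$n_hh, b$n_out))
    }) %>% list_rbind()
    if (bonferroni) pairwise$p_fisher <- pmin(1, pairwise$p_fisher * nrow(pairwise))
  }
  freq_test <- NULL
  if (sum(alleles$in_region) > 0 && sum(!alleles$in_region) > 0) {
    wt <- wilcox.test(alleles$freq[alleles$in_region],
                      alleles$freq[!alleles$in_region], exact = FALSE)
    freq_test <- tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  or_test <- NULL
  if ("odds_ratio" %in% names(alleles) && any(!is.na(alleles$odds_ratio))) {
    a <- alleles %>% filter(!is.na(.data$odds_ratio))
    hi_in <- sum(a$in_region & a$odds_ratio > or_threshold)
    hi_out <- sum(!a$in_region & a$odds_ratio > or_threshold)
    n_in <- sum(a$in_region); n_out <- sum(!a$in_region)
    if (n_in > 0 && n_out > 0) {
      or_test <- tibble(
        prop_hh = hi_in / n_in, prop_out = hi_out / n_out,
        p_fisher = fisher_one_sided(hi_in, n_in - hi_in, hi_out, n_out - hi_out)
      )
    }
  }
  structure(list(categories = categories, pairwise = pairwise,
                 freq_test = freq_test, or_test = or_test),
            class = "disease_overlap")
}
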