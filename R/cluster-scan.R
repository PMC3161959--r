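#' Poisson sliding-window scan for clusters of deleterious SNPs
#'
#' Scans `window_size` windows at `step` intervals across the genome and
#' tests each for an excess of deleterious SNPs relative to the accessible
#' coding sequence it contains, assuming a genome-wide constant rate. The
#' expected count per window is the genome-average rate (total deleterious
#' SNPs / total accessible CDS kb, computed from the data, never supplied)
#' times the window's accessible CDS kb; the upper-tail probability
#' `P(X >= k)` under Poisson(lambda) scores the excess. Windows with fewer
#' than `min_snps` deleterious SNPs are ineligible. The most significant
#' `top_frac` of eligible windows are selected (ties at the boundary p
#' included) and overlapping or boundary-sharing selected windows are
#' merged, keeping the smallest-p window as each region's representative
#' and extending its coordinates to the union.
#'
#' @param snps Tibble with `chrom`, `pos`, `call` (`"DEL"` rows are
#'   counted).
#' @param mask Accessible-CDS mask tibble (`chrom`, `start`, `end`); must
#'   be non-empty.
#' @param chrom_info Optional tibble `chrom`, `length`; defaults to the
#'   mask extent per chromosome.
#' @param window_size,step Window width and step in bp (1 Mb / 0.5 Mb).
#' @param top_frac Fraction of eligible windows selected (default 2%).
#' @param min_snps Minimum deleterious SNPs for eligibility (default 2).
#' @return A list of class `cluster_scan`: `windows` (all scanned windows
#'   with `k`, `lambda`, `p`, `eligible`, `selected`), `regions` (merged
#'   selected regions with the representative window's `p`), and
#'   `rate_per_kb` (the genome average used).
#' @export
scan_clusters <- function(snps, mask, chrom_info = NULL,
                          window_size = 1e6, step = 5e5,
                          top_frac = 0.02, min_snps = 2) {
  if (nrow(mask) == 0) abort("accessible mask must be non-empty")
  del <- snps %>% filter(.data$call == "DEL")
  total_kb <- sum(mask$end - mask$start) / 1000
  if (total_kb <= 0) abort("accessible mask has zero total length")
  rate <- nrow(del) / total_kb
  if (is.null(chrom_info)) {
    chrom_info <- mask %>%
      group_by(.data$chrom) %>%
      summarise(length = max(.data$end), .groups = "drop")
  }
  windows <- chrom_info %>%
    group_by(.data$chrom) %>%
    reframe(start = seq(0, max(.data$length - 1, 0), by = step)) %>%
    left_join(chrom_info, by = "chrom") %>%
    mutate(end = pmin(.data$start + window_size, .data$length)) %>%
    select("chrom", "start", "end")
  windows$cds_kb <- window_mask_overlap(windows, mask) / 1000
  counts <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    p <- del$pos[del$chrom == ch]
    if (length(p) == 0) next
    counts[idx] <- vapply(idx, function(i) {
      sum(p > windows$start[i] & p <= windows$end[i])
    }, integer(1))
  }
  windows <- windows %>%
    mutate(
      k = counts,
      lambda = rate * .data$cds_kb,
      p = ppois(.data$k - 1, .data$lambda, lower.tail = FALSE),
      eligible = .data$k >= min_snps
    )
  elig <- windows %>% filter(.data$eligible)
  if (nrow(elig) == 0) {
    warn("no eligible windows")
    return(structure(list(windows = windows %>% mutate(selected = FALSE),
                          regions = tibble(chrom = character(), start = numeric(),
                                           end = numeric(), p = numeric()),
                          rate_per_kb = rate),
                     class = "cluster_scan"))
  }
  n_sel <- max(1L, floor(top_frac * nrow(elig)))
  p_thr <- sort(elig$p)[n_sel]
  windows <- windows %>% mutate(selected = .data$eligible & .data$p <= p_thr)
  sel <- windows %>% filter(.data$selected) %>% arrange(.data$chrom, .data$start)
  regions <- sel %>%
    group_by(.data$chrom) %>%
    group_modify(function(d, key) {
      grp <- cumsum(c(TRUE, d$start[-1] > d$end[-nrow(d)]))
      d %>%
        mutate(grp = grp) %>%
        group_by(.data$grp) %>%
        summarise(start = min(.data$start), end = max(.data$end),
                  p = min(.data$p), k = .data$k[which.min(.data$p)],
                  .groups = "drop") %>%
        select(-"grp")
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start)
  structure(list(windows = windows, regions = regions, rate_per_kb = rate),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf(
    "Poisson cluster scan: %d windows (%d eligible), %d selected, %d merged regions\n",
    nrow(x$windows), sum(x$windows$eligible), sum(x$windows$selected),
    nrow(x$regions)))
  cat(sprintf("genome-average rate: %.4g deleterious SNPs per kb accessible CDS\n",
              x$rate_per_kb))
  invisible(x)
}
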