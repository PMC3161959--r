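#' Recombination rate of one genomic window
#'
#' The window rate is the genetic-map distance between the two most distant
#' map points in the window divided by their physical distance (cM/Mb).
#' The window is excluded when those two points are not more than
#' `min_span` apart (too little of the window is informative).
#'
#' @param window_map Tibble of map points inside the window: columns `pos`
#'   (bp) and `cM` (cumulative).
#' @param min_span Minimum bp separation of the extreme map points
#'   (default 360 kb).
#' @return A one-row tibble: `rec_rate` (cM/Mb, `NA` when excluded),
#'   `span`, `excluded`, `reason`.
#' @export
window_rec_rate <- function(window_map, min_span = 360e3) {
  if (nrow(window_map) >= 2 && is.unsorted(window_map$cM[order(window_map$pos)])) {
    abort("genetic map must be non-decreasing in position")
  }
  if (nrow(window_map) < 2) {
    return(tibble(rec_rate = NA_real_, span = NA_real_, excluded = TRUE,
                  reason = "fewer than two map points"))
  }
  i <- which.min(window_map$pos)
  j <- which.max(window_map$pos)
  span <- window_map$pos[j] - window_map$pos[i]
  if (span <= min_span) {
    return(tibble(rec_rate = NA_real_, span = span, excluded = TRUE,
                  reason = sprintf("map span %.0f bp <= %.0f bp", span, min_span)))
  }
  rate <- (window_map$cM[j] - window_map$cM[i]) / (span / 1e6)
  tibble(rec_rate = rate, span = span, excluded = FALSE, reason = NA_character_)
}

#' Non-overlapping recombination-rate windows across the genome
#'
#' Tiles each chromosome with `window_size` windows, estimates each
#' window's recombination rate with [window_rec_rate()], and applies the
#' exclusion rules: insufficient map span, within `end_buffer` of a
#' chromosome end or centromere edge, or no aligned coding sequence.
#'
#' @param map Genetic map tibble: `chrom`, `pos` (bp), `cM` (cumulative).
#' @param chrom_info Tibble `chrom`, `length`, and optionally
#'   `centro_start`, `centro_end` (bp).
#' @param cds Aligned-CDS mask tibble (`chrom`, `start`, `end`), used both
#'   for the no-CDS exclusion and to report aligned bp per window.
#' @param window_size Window width in bp (default 400 kb).
#' @param min_span See [window_rec_rate()].
#' @param end_buffer Exclusion buffer around chromosome ends and
#'   centromeres (default 10 Mb).
#' @return Tibble of windows: `chrom`, `start`, `end`, `rec_rate`,
#'   `cds_bp`, `excluded`, `reason`.
#' @export
rec_rate_windows <- function(map, chrom_info, cds, window_size = 400e3,
                             min_span = 360e3, end_buffer = 10e6) {
  wins <- chrom_info %>%
    group_by(.data$chrom) %>%
    reframe(start = seq(0, .data$length - 1, by = window_size)) %>%
    left_join(chrom_info, by = "chrom") %>%
    mutate(end = pmin(.data$start + window_size, .data$length))
  rates <- wins %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    group_modify(function(d, key) {
      pts <- map %>%
        filter(.data$chrom == key$chrom, .data$pos >= key$start, .data$pos < key$end)
      window_rec_rate(pts %>% select("pos", "cM"), min_span = min_span)
    }) %>%
    ungroup()
  out <- wins %>%
    left_join(rates, by = c("chrom", "start", "end")) %>%
    mutate(cds_bp = window_mask_overlap(., cds))
  near_end <- out$start < end_buffer | out$end > out$length - end_buffer
  if (all(c("centro_start", "centro_end") %in% names(out))) {
    near_end <- near_end |
      (out$start < out$centro_end + end_buffer & out$end > out$centro_start - end_buffer)
  }
  out %>%
    mutate(
      reason = case_when(
        near_end ~ "within end/centromere buffer",
        .data$cds_bp <= 0 ~ "no aligned coding sequence",
        TRUE ~ .data$reason
      ),
      excluded = .data$excluded | near_end | .data$cds_bp <= 0
    ) %>%
    select("chrom", "start", "end", "rec_rate", "cds_bp", "excluded", "reason")
}

#' Assign retained windows to equal-sized recombination bins
#'
#' Ranks non-excluded windows by recombination rate and splits them into
#' `n_bins` equal-sized bins (sizes differing by at most one window).
#'
#' @param windows Output of [rec_rate_windows()].
#' @param n_bins Number of bins (default 10).
#' @return The retained windows with `bin` (1 = lowest recombination) and
#'   the bin mean rate `r_bin`.
#' @export
rec_bins <- function(windows, n_bins = 10) {
  kept <- windows %>% filter(!.data$excluded)
  if (nrow(kept) < n_bins) abort("fewer retained windows than bins")
  kept %>%
    arrange(.data$rec_rate) %>%
    mutate(bin = ntile(row_number(), n_bins)) %>%
    group_by(.data$bin) %>%
    mutate(r_bin = mean(.data$rec_rate)) %>%
    ungroup()
}

#' Conservation-adjustment offset for SNP-ratio regressions
#'
#' For recombination bin `i` and codon GC class `j`, the offset cell is the
#' class-wide deleterious fraction rescaled by the bin's relative
#' conservation density:
#' \deqn{s_{i,j} = fdel_j \cdot fcon_{i,j} / \overline{fcon}_j}
#' where `fcon_ij` is the fraction of conserved codons among aligned codons
#' with `j` GC nucleotides in bin `i`, `fcon_j` its mean over bins, and
#' `fdel_j` the fraction of deleterious calls among tested nonsynonymous
#' SNPs in class `j`. Cells are clipped to `(eps, 1 - eps)` before the
#' logit enters the model as a fixed offset.
#'
#' @param cells Tibble with one row per (`bin`, `gc_class`) and columns
#'   `n_codons`, `n_conserved`, `del`, `neu`.
#' @param eps Clipping bound (default `1e-6`).
#' @return The cells with `fcon`, `fcon_class`, `fdel_class`, and the
#'   clipped offset `s_off`; cells with no aligned codons are flagged
#'   `missing_cell` and excluded from fits.
#' @export
conservation_offset <- function(cells, eps = 1e-6) {
  cells %>%
    mutate(fcon = ifelse(.data$n_codons > 0, .data$n_conserved / .data$n_codons, NA_real_)) %>%
    group_by(.data$gc_class) %>%
    mutate(
      fcon_class = mean(.data$fcon, na.rm = TRUE),
      fdel_class = sum(.data$del) / pmax(sum(.data$del) + sum(.data$neu), 1)
    ) %>%
    ungroup() %>%
    mutate(
      s_off = pmin(pmax(.data$fdel_class * .data$fcon / .data$fcon_class, eps), 1 - eps),
      missing_cell = .data$n_codons <= 0
    )
}

new_sweep_glm <- function(fit, model, data, offset_used) {
  structure(
    list(fit = fit, model = model, data = data, offset = offset_used,
         converged = fit$converged),
    class = "sweep_glm"
  )
}

#' @export
print.sweep_glm <- function(x, ...) {
  cat(sprintf("Binomial logistic fit (%s model)%s\n", x$model,
              if (x$offset) " with conservation offset" else ""))
  print(tidy(x))
  invisible(x)
}

#' Logistic regression of the deleterious fraction on recombination rate
#'
#' Fits the binomial model in which cell (`i`, `j`) contributes `DEL`
#' successes out of `DEL + NEU` trials with linear predictor
#' `logit(s_ij) + b0 + b1 * r_i`, the offset term fixed. A negative `b1`
#' means the deleterious fraction falls as recombination rises.
#'
#' @param cells Output of [conservation_offset()] (needs `del`, `neu`,
#'   `r_bin`, `s_off`, `missing_cell`).
#' @return A `sweep_glm` object; see [tidy.sweep_glm()].
#' @export
fit_recombination_model <- function(cells) {
  d <- cells %>% filter(!.data$missing_cell, .data$del + .data$neu > 0)
  if (nrow(d) < 2) abort("need >= 2 informative cells")
  fit <- glm(cbind(del, neu) ~ r_bin, family = binomial(),
             offset = qlogis(s_off), data = d)
  if (!fit$converged) abort("recombination model failed to converge")
  new_sweep_glm(fit, "recombination", d, TRUE)
}

#' Logistic regression with a hitchhiking-window indicator
#'
#' As [fit_recombination_model()] with an added indicator `h` for windows
#' overlapping hitchhiking regions: linear predictor
#' `logit(s) + b0 + b1 * r + b2 * h`. Cells must carry an `h` column in
#' `{0, 1}` (windows overlapping regions found by at least the configured
#' number of tests get 1; windows overlapping none get 0; others are
#' dropped before aggregation).
#'
#' @param cells Offset cells with columns `del`, `neu`, `r_bin`, `s_off`,
#'   `h`, `missing_cell`.
#' @return A `sweep_glm` object with coefficient `h`.
#' @export
fit_hitchhiking_model <- function(cells) {
  d <- cells %>% filter(!.data$missing_cell, .data$del + .data$neu > 0)
  if (length(unique(d$h)) < 2) abort("degenerate design: need both h = 0 and h = 1 cells")
  fit <- glm(cbind(del, neu) ~ r_bin + h, family = binomial(),
             offset = qlogis(s_off), data = d)
  if (!fit$converged) abort("hitchhiking model failed to converge")
  new_sweep_glm(fit, "hitchhiking", d, TRUE)
}

#' Logistic regression of the deleterious fraction on distance
#'
#' Models the per-bin deleterious fraction `DEL / (DEL + NEU)` as
#' `b0 + b1 * d_k` on the logit scale, where `d_k` is the bin's distance
#' (Mb) from the nearest hitchhiking region. A negative `b1` is the
#' distance decay expected when hitchhiking locally enriches deleterious
#' relative to neutral polymorphism.
#'
#' @param bins Tibble with `distance_mb`, `del`, `neu` (one row per
#'   distance bin, regions themselves excluded).
#' @return A `sweep_glm` object with coefficient `distance_mb`.
#' @export
fit_distance_model <- function(bins) {
  d <- bins %>% filter(.data$del + .data$neu > 0)
  if (nrow(d) < 2) abort("need >= 2 informative distance bins")
  fit <- glm(cbind(del, neu) ~ distance_mb, family = binomial(), data = d)
  if (!fit$converged) abort("distance model failed to converge")
  new_sweep_glm(fit, "distance", d, FALSE)
}

#' Exclude SNPs potentially affected by biased gene conversion
#'
#' Removes SNPs whose ancestral-to-derived change is A/T to G/C (the
#' direction favoured by GC-biased gene conversion, which mimics positive
#' selection near recombination) and SNPs within codons containing zero GC
#' nucleotides. SNPs with unknown ancestral state are dropped and counted.
#'
#' @param snps Tibble with `ancestral`, `derived` (bases) and `gc_class`.
#' @return The filtered tibble, with exclusion counts in attribute
#'   `"exclusions"` (`at_gc`, `gc0`, `unknown_ancestral`).
#' @export
bgc_filter <- function(snps) {
  known <- snps$ancestral %in% c("A", "C", "G", "T") &
    snps$derived %in% c("A", "C", "G", "T")
  at_gc <- known & snps$ancestral %in% c("A", "T") & snps$derived %in% c("G", "C")
  gc0 <- !is.na(snps$gc_class) & snps$gc_class == 0
  keep <- known & !at_gc & !gc0
  out <- snps[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(
    at_gc = sum(at_gc, na.rm = TRUE),
    gc0 = sum(gc0 & known & !at_gc, na.rm = TRUE),
    unknown_ancestral = sum(!known)
  )
  out
}

#' Label recombination windows by hitchhiking status
#'
#' Windows overlapping a region identified by at least `min_tests` tests
#' get `h = 1`; windows overlapping no region at all get `h = 0`; windows
#' overlapping only weaker regions get `NA` and are dropped from the
#' hitchhiking regression.
#'
#' @param windows Window tibble (`chrom`, `start`, `end`).
#' @param regions Region tibble with an `n_tests` column.
#' @param min_tests Minimum test count for the hitchhiking group
#'   (default 3).
#' @return `windows` with an added `h` column (`1`, `0`, or `NA`).
#' @export
label_hitchhiking_windows <- function(windows, regions, min_tests = 3) {
  strong <- regions %>% filter(.data$n_tests >= min_tests)
  mid_any <- windows %>%
    mutate(pos = NA) %>%
    select("chrom", "start", "end")
  ov_any <- window_mask_overlap(mid_any, regions %>% select("chrom", "start", "end")) > 0
  ov_strong <- if (nrow(strong) > 0) {
    window_mask_overlap(mid_any, strong %>% select("chrom", "start", "end")) > 0
  } else rep(FALSE, nrow(windows))
  windows %>%
    mutate(h = case_when(ov_strong ~ 1, !ov_any ~ 0, TRUE ~ NA_real_))
}

#' Aggregate SNPs and codon conservation into bin-by-GC cells
#'
#' Joins classified SNPs and per-codon conservation onto the binned
#' recombination windows and aggregates `DEL`/`NEU` counts and
#' conserved-codon fractions per (bin, GC class) cell — the layout consumed
#' by [conservation_offset()] and the regression fits. When the windows
#' carry an `h` label ([label_hitchhiking_windows()]), cells are formed per
#' (bin, GC class, h) and windows with `h = NA` are dropped.
#'
#' @param bins Binned windows from [rec_bins()] (optionally labelled with
#'   `h`).
#' @param snps Classified SNP tibble (`chrom`, `pos`, `call`, `gc_class`).
#' @param codons Codon annotation tibble (`chrom`, `start`, `gc_class`,
#'   `conserved`).
#' @return A tibble of cells: grouping columns, `r_bin`, `del`, `neu`,
#'   `n_codons`, `n_conserved`.
#' @export
gc_conservation_cells <- function(bins, snps, codons) {
  use_h <- "h" %in% names(bins)
  if (use_h) bins <- bins %>% filter(!is.na(.data$h))
  # containment join per chromosome (windows are disjoint)
  assign_win <- function(chrom, pos0) {
    out <- rep(NA_integer_, length(pos0))
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      b <- bins %>% filter(.data$chrom == ch) %>% arrange(.data$start)
      if (nrow(b) == 0) next
      iv <- findInterval(pos0[idx], b$start)
      ok <- iv >= 1 & pos0[idx] < b$end[pmax(iv, 1)]
      out[idx[ok]] <- which(bins$chrom == ch)[order(b$start)][iv[ok]]
    }
    out
  }
  snps <- snps %>% filter(.data$call %in% c("DEL", "NEU"))
  snps$win_row <- assign_win(snps$chrom, snps$pos - 1)
  codons$win_row <- assign_win(codons$chrom, codons$start)
  grouping <- if (use_h) c("bin", "h", "gc_class") else c("bin", "gc_class")
  snp_cells <- snps %>%
    filter(!is.na(.data$win_row)) %>%
    mutate(bin = bins$bin[.data$win_row],
           h = if (use_h) bins$h[.data$win_row] else NULL) %>%
    group_by(across(all_of(grouping))) %>%
    summarise(del = sum(.data$call == "DEL"),
              neu = sum(.data$call == "NEU"), .groups = "drop")
  codon_cells <- codons %>%
    filter(!is.na(.data$win_row)) %>%
    mutate(bin = bins$bin[.data$win_row],
           h = if (use_h) bins$h[.data$win_row] else NULL) %>%
    group_by(across(all_of(grouping))) %>%
    summarise(n_codons = dplyr::n(),
              n_conserved = sum(.data$conserved), .groups = "drop")
  r_tbl <- bins %>% distinct(.data$bin, .data$r_bin)
  full_join(codon_cells, snp_cells, by = grouping) %>%
    mutate(del = coalesce(.data$del, 0L), neu = coalesce(.data$neu, 0L)) %>%
    left_join(r_tbl, by = "bin") %>%
    arrange(across(all_of(grouping)))
}
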