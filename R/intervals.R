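# Interval utilities shared by the enrichment, window, and scan modules.
# Regions and masks are tibbles with chrom/start/end in 0-based half-open
# coordinates; IRanges does the overlap, distance, and merge work behind
# the tibble surface (converted to 1-based closed internally).

as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Round region boundaries to a 10-kb grid, preserving containment
#'
#' Expands each interval outwards to the enclosing multiples of `grid`:
#' start rounded down, end rounded up. Rounding to the *nearest* grid point
#' could shrink an interval and drop SNPs it originally contained, so the
#' containment-preserving convention is used.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param grid Grid size in bp (default 10 kb).
#' @return The tibble with rounded `start`/`end`.
#' @export
round_regions <- function(regions, grid = 1e4) {
  regions %>%
    mutate(start = floor(.data$start / grid) * grid,
           end = ceiling(.data$end / grid) * grid)
}

#' Merge overlapping intervals within a region set
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @return Tibble of disjoint merged intervals, sorted.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  regions %>%
    group_by(.data$chrom) %>%
    group_modify(function(d, key) {
      r <- IRanges::reduce(as_iranges(d))
      tibble(start = BiocGenerics::start(r) - 1, end = BiocGenerics::end(r))
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start)
}

# total bp of `mask` falling inside / outside `regions`, per side
mask_split_lengths <- function(mask, regions) {
  mask <- merge_regions(mask)
  regions <- merge_regions(regions)
  total <- sum(mask$end - mask$start)
  inside <- sum(map_dbl(unique(mask$chrom), function(ch) {
    m <- mask %>% filter(.data$chrom == ch)
    r <- regions %>% filter(.data$chrom == ch)
    if (nrow(r) == 0) return(0)
    ov <- IRanges::intersect(as_iranges(m), as_iranges(r))
    sum(BiocGenerics::width(ov))
  }))
  c(inside = inside, outside = total - inside)
}

# logical: does each point (chrom, pos; 1-based bp) fall inside regions?
points_in_regions <- function(points, regions) {
  res <- rep(FALSE, nrow(points))
  regions <- merge_regions(regions)
  for (ch in unique(points$chrom)) {
    idx <- which(points$chrom == ch)
    r <- regions %>% filter(.data$chrom == ch)
    if (nrow(r) == 0) next
    q <- IRanges::IRanges(points$pos[idx], points$pos[idx])
    res[idx] <- IRanges::overlapsAny(q, as_iranges(r))
  }
  res
}

# distance (bp) from each point to the nearest region edge; 0 inside.
# Points on chromosomes with no regions get NA.
points_region_distance <- function(points, regions) {
  out <- rep(NA_real_, nrow(points))
  regions <- merge_regions(regions)
  for (ch in unique(points$chrom)) {
    idx <- which(points$chrom == ch)
    r <- regions %>% filter(.data$chrom == ch)
    if (nrow(r) == 0) next
    q <- IRanges::IRanges(points$pos[idx], points$pos[idx])
    hit <- IRanges::distanceToNearest(q, as_iranges(r))
    d <- rep(NA_real_, length(idx))
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    out[idx] <- d
  }
  out
}

# bp of overlap between each window (w: chrom,start,end) and a mask
window_mask_overlap <- function(windows, mask) {
  mask <- merge_regions(mask)
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    m <- mask %>% filter(.data$chrom == ch)
    if (nrow(m) == 0) next
    w <- IRanges::IRanges(windows$start[idx] + 1, windows$end[idx])
    ov <- IRanges::findOverlaps(w, as_iranges(m))
    if (length(ov) == 0) next
    wid <- BiocGenerics::width(IRanges::pintersect(
      w[S4Vectors::queryHits(ov)], as_iranges(m)[S4Vectors::subjectHits(ov)]))
    agg <- tapply(wid, S4Vectors::queryHits(ov), sum)
    out[idx[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}
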