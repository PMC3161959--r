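#' Diversity estimators from a site frequency spectrum
#'
#' Computes Watterson's `theta_w`, the average pairwise heterozygosity
#' `theta_pi`, and Fay and Wu's `theta_h` from an unfolded site frequency
#' spectrum over derived allele counts `1..n-1` in a sample of `n`
#' chromosomes. All three estimate the population-scaled mutation rate
#' `4*N*u` under neutrality; they weight low-, intermediate-, and
#' high-frequency derived variants respectively:
#' \deqn{\theta_W = S / a_n, \quad a_n = \sum_{i=1}^{n-1} 1/i}
#' \deqn{\theta_\pi = \sum_i S_i \, 2 i (n - i) / (n (n-1))}
#' \deqn{\theta_H = \sum_i S_i \, 2 i^2 / (n (n-1))}
#' where `S_i` is the number of sites with derived count `i`. Sites fixed in
#' the sample (count `n`) are substitutions, not polymorphisms, and must not
#' appear in the spectrum.
#'
#' @param sfs Either an integer vector of length `n - 1` (`sfs[i]` = number
#'   of sites at derived count `i`) or a data frame with columns
#'   `derived_count` and `n_sites`.
#' @param n Sample size in chromosomes (`>= 2`).
#' @return A one-row tibble with columns `theta_w`, `theta_pi`, `theta_h`,
#'   `S`, `n`, and `a_n`.
#' @examples
#' theta_estimates(c(10, rep(0, 98)), n = 100)
#' @export
theta_estimates <- function(sfs, n) {
  if (n < 2) abort("sample size n must be >= 2")
  if (is.data.frame(sfs)) {
    counts <- numeric(n - 1)
    i <- sfs$derived_count
    if (any(i < 1 | i > n - 1)) {
      abort("derived_count must lie in 1..n-1 (fixed sites are excluded from spectra)")
    }
    counts[i] <- counts[i] + sfs$n_sites
    sfs <- counts
  }
  if (length(sfs) != n - 1) {
    abort(sprintf("spectrum must have length n - 1 = %d, got %d", n - 1, length(sfs)))
  }
  if (any(sfs < 0)) abort("spectrum entries must be >= 0")
  i <- seq_len(n - 1)
  a_n <- sum(1 / i)
  S <- sum(sfs)
  tibble(
    theta_w  = S / a_n,
    theta_pi = sum(sfs * 2 * i * (n - i)) / (n * (n - 1)),
    theta_h  = sum(sfs * 2 * i^2) / (n * (n - 1)),
    S = S, n = n, a_n = a_n
  )
}

#' Per-class diversity estimators from a class-stratified spectrum
#'
#' Applies [theta_estimates()] separately to each mutation class of a long
#' spectrum table, carrying along any extra grouping columns (`rep`,
#' `epoch`, `rho`, `phase`, ...).
#'
#' @param sfs A data frame with columns `mclass`, `derived_count`,
#'   `n_sites`, plus optional grouping columns.
#' @param n Sample size in chromosomes.
#' @return A tibble with one row per group x class and the five estimator
#'   columns of [theta_estimates()].
#' @export
class_thetas <- function(sfs, n) {
  extra <- setdiff(names(sfs), c("derived_count", "n_sites"))
  sfs %>%
    group_by(across(all_of(extra))) %>%
    group_modify(~ theta_estimates(.x, n = n)) %>%
    ungroup()
}

#' Ratio of a diversity estimator between two mutation classes
#'
#' Returns `theta_x(numerator class) / theta_x(denominator class)` for one
#' estimator. A zero denominator yields `NA` with a warning so that callers
#' can exclude the replicate from aggregation (and log how many were
#' dropped), rather than propagating an infinity.
#'
#' @param num,den One-row data frames as returned by [theta_estimates()]
#'   (numerator and denominator class).
#' @param which Estimator name: `"theta_w"`, `"theta_pi"`, or `"theta_h"`.
#' @return A single number (possibly `NA`).
#' @export
class_ratio <- function(num, den, which = c("theta_pi", "theta_w", "theta_h")) {
  which <- match.arg(which)
  d <- den[[which]]
  if (!isTRUE(d > 0)) {
    warn(sprintf("denominator %s is zero; ratio flagged NA", which))
    return(NA_real_)
  }
  num[[which]] / d
}

#' Aggregate per-replicate diversity estimates
#'
#' Means and standard errors of each estimator across replicates, by
#' mutation class and any other grouping columns present (e.g. `rho`,
#' `phase`). This is the aggregation used for sweep-curve summaries.
#'
#' @param thetas A tibble as returned by [class_thetas()] over many
#'   replicates, containing a `rep` column.
#' @return A long tibble with columns `estimator`, `mean`, `se`, `n_reps`
#'   per group.
#' @export
aggregate_thetas <- function(thetas) {
  extra <- setdiff(
    names(thetas),
    c("rep", "theta_w", "theta_pi", "theta_h", "S", "n", "a_n")
  )
  thetas %>%
    pivot_longer(c("theta_w", "theta_pi", "theta_h"),
                 names_to = "estimator", values_to = "theta") %>%
    group_by(across(all_of(c(extra, "estimator")))) %>%
    summarise(
      mean = mean(.data$theta),
      se = sd(.data$theta) / sqrt(dplyr::n()),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}

#' Deleterious-to-neutral ratio of replicate-mean diversity
#'
#' Computes the class ratio of an estimator as the ratio of replicate means
#' (mean over replicates within class first, then ratio). Per-replicate
#' ratios are unstable whenever a replicate has no neutral polymorphism, so
#' the ratio of means is the aggregation used for sweep-curve ratio panels.
#' Replicates are never dropped by this path; zero *mean* denominators
#' still flag `NA` with a warning.
#'
#' @param thetas Per-replicate tibble from [class_thetas()] with an
#'   `mclass` column.
#' @param which Estimator name.
#' @param num_class,den_class Mutation classes to contrast.
#' @return A tibble with one row per residual grouping (e.g. `rho`,
#'   `phase`) and a `ratio` column.
#' @export
aggregate_class_ratio <- function(thetas, which = c("theta_pi", "theta_w", "theta_h"),
                                  num_class = "deleterious", den_class = "neutral") {
  which <- match.arg(which)
  extra <- setdiff(
    names(thetas),
    c("rep", "mclass", "theta_w", "theta_pi", "theta_h", "S", "n", "a_n")
  )
  means <- thetas %>%
    filter(.data$mclass %in% c(num_class, den_class)) %>%
    group_by(across(all_of(c(extra, "mclass")))) %>%
    summarise(mean = mean(.data[[which]]), .groups = "drop") %>%
    pivot_wider(names_from = "mclass", values_from = "mean")
  out <- means %>%
    mutate(ratio = ifelse(.data[[den_class]] > 0,
                          .data[[num_class]] / .data[[den_class]], NA_real_)) %>%
    select(all_of(extra), ratio = "ratio")
  if (anyNA(out$ratio)) warn("zero mean denominator; ratio flagged NA")
  out
}
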