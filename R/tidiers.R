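# broom-style methods for the package's fitted/result objects.

#' Tidy a logistic enrichment fit
#'
#' One row per model term with estimate, standard error, Wald statistic
#' and p-value.
#'
#' @param x A `sweep_glm` from [fit_recombination_model()],
#'   [fit_hitchhiking_model()], or [fit_distance_model()].
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.sweep_glm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"]
  )
}

#' @rdname tidy.sweep_glm
#' @export
glance.sweep_glm <- function(x, ...) {
  f <- x$fit
  tibble(
    model = x$model,
    null_deviance = f$null.deviance,
    deviance = f$deviance,
    df_residual = f$df.residual,
    aic = f$aic,
    n_cells = nrow(x$data),
    converged = x$converged,
    offset_used = x$offset
  )
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result` (already tabular; returned as a plain
#'   tibble).
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a cluster scan
#'
#' @param x A `cluster_scan`; returns the merged regions.
#' @param ... Unused.
#' @export
tidy.cluster_scan <- function(x, ...) x$regions

#' @rdname tidy.cluster_scan
#' @export
glance.cluster_scan <- function(x, ...) {
  tibble(
    n_windows = nrow(x$windows),
    n_eligible = sum(x$windows$eligible),
    n_selected = sum(x$windows$selected),
    n_regions = nrow(x$regions),
    rate_per_kb = x$rate_per_kb
  )
}

#' Tidy an iHS scan
#'
#' @param x An `ihs_scan`; returns the merged outlier regions.
#' @param ... Unused.
#' @export
tidy.ihs_scan <- function(x, ...) x$regions
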