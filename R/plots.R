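# ggplot2 display methods for result objects.

#' Plot sweep-study diversity curves
#'
#' Mean diversity by recombination parameter, estimator, class, and phase
#' (pre/post sweep, or sweeps/control), mirroring the standard layout of
#' hitchhiking simulation summaries.
#'
#' @param object A `wf_study` tibble from [sweep_study()].
#' @param classes Mutation classes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wf_study <- function(object, classes = c("neutral", "deleterious"), ...) {
  agg <- aggregate_thetas(object %>% filter(.data$mclass %in% classes))
  ggplot2::ggplot(agg, ggplot2::aes(
    x = .data$rho + min(agg$rho[agg$rho > 0], 1) / 10,
    y = .data$mean, colour = .data$estimator, linetype = .data$phase
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$mclass)) +
    ggplot2::labs(x = "recombination parameter (population events/generation)",
                  y = "diversity (units of 4Nu)")
}

#' Plot deleterious-to-neutral ratio curves
#'
#' Ratio of replicate-mean deleterious to neutral diversity against the
#' recombination parameter, per phase.
#'
#' @param study A `wf_study` tibble from [sweep_study()].
#' @param which Estimator.
#' @return A ggplot.
#' @export
plot_class_ratio <- function(study, which = "theta_pi") {
  rat <- aggregate_class_ratio(study, which = which)
  ggplot2::ggplot(rat, ggplot2::aes(
    x = .data$rho + min(rat$rho[rat$rho > 0], 1) / 10,
    y = .data$ratio, colour = .data$phase
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "recombination parameter (population events/generation)",
                  y = sprintf("deleterious / neutral %s", which))
}

#' Plot enrichment folds with confidence bars
#'
#' @param object An `enrichment_result` (possibly multi-row, e.g. from
#'   [freq_class_ratios()] or [enrichment_from_counts()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- as_tibble(unclass(object))
  lab <- names(d)[!names(d) %in% c(
    "del_hh", "neu_hh", "del_out", "neu_out", "del_density_hh",
    "neu_density_hh", "del_density_out", "neu_density_out", "ratio_hh",
    "ratio_out", "fold", "fold_lo", "fold_hi", "conf_level", "z", "p_z",
    "p_fisher")]
  d$stratum <- if (length(lab) > 0) do.call(paste, d[lab]) else "all"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stratum, y = .data$fold)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold_lo, ymax = .data$fold_hi),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "fold enrichment (hitchhiking / other)")
}

#' @rdname autoplot.enrichment_result
#' @export
autoplot.freq_class_result <- autoplot.enrichment_result

#' Plot the distance decay of the deleterious fraction
#'
#' Per-bin deleterious fraction against distance from the nearest
#' hitchhiking region, with the fitted logistic decay overlaid; circle
#' area reflects the bin's SNP count.
#'
#' @param bins The `bins` tibble from [distance_bins()].
#' @param fit Optional `sweep_glm` from [fit_distance_model()].
#' @return A ggplot.
#' @export
plot_distance_decay <- function(bins, fit = NULL) {
  d <- bins %>% mutate(frac = .data$del / (.data$del + .data$neu))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_mb, y = .data$frac)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$del + .data$neu,
                                     colour = .data$in_region)) +
    ggplot2::scale_size_area() +
    ggplot2::labs(x = "distance to nearest hitchhiking region (Mb)",
                  y = "deleterious fraction of nonsynonymous SNPs",
                  size = "SNPs")
  if (!is.null(fit)) {
    xs <- seq(0, max(d$distance_mb), length.out = 100)
    co <- coef(fit$fit)
    pred <- tibble(distance_mb = xs, frac = plogis(co[1] + co[2] * xs))
    p <- p + ggplot2::geom_line(data = pred, colour = "grey40")
  }
  p
}

#' Plot a cluster scan along the genome
#'
#' @param object A `cluster_scan`.
#' @param ... Unused.
#' @return A ggplot of -log10 p per window with selected regions shaded.
#' @export
autoplot.cluster_scan <- function(object, ...) {
  w <- object$windows %>% filter(.data$eligible)
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                  y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(-log[10] ~ "Poisson tail p"))
}
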