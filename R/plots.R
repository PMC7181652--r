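#' Plot an SPD, optionally against its null envelope
#'
#' @param object An `spd` tibble from [sum_spd()].
#' @param envelope Optional `spd_null` from [simulate_null()] on the same
#'   grid; drawn as a ribbon with the null mean as a line.
#' @param ... Unused.
#' @return A ggplot. The x axis runs old to young, the field convention.
#' @method autoplot spd
#' @export
autoplot.spd <- function(object, envelope = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cal_bp, y = .data$density))
  if (!is.null(envelope)) {
    p <- p +
      ggplot2::geom_ribbon(data = envelope,
                           ggplot2::aes(x = .data$cal_bp, ymin = .data$lower,
                                        ymax = .data$upper),
                           inherit.aes = FALSE, fill = "grey80") +
      ggplot2::geom_line(data = envelope,
                         ggplot2::aes(x = .data$cal_bp, y = .data$mean),
                         inherit.aes = FALSE, colour = "black")
  }
  p + ggplot2::geom_line(colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "cal yr BP", y = "summed probability",
                  title = sprintf("SPD of %s dates", attr(object, "n_dates")))
}

#' Plot a multi-site z-score composite with its lowess smooth
#'
#' @param object A [composite_zscores()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot composite_series
#' @export
autoplot.composite_series <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$cal_bp, y = .data$z,
                               colour = .data$site)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = object$smooth,
                       ggplot2::aes(x = .data$cal_bp, y = .data$value),
                       inherit.aes = FALSE, linewidth = 0.9) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "cal yr BP", y = "flux z-score",
                  title = sprintf("composite (lowess span %g)", object$span))
}

#' Diagnostic plot for a WA-PLS fit: observed vs fitted
#'
#' @param object A [wapls()] fit.
#' @param k Component count to show (default the fitted number).
#' @param ... Unused.
#' @return A ggplot on the transformed environmental scale.
#' @method autoplot wapls
#' @export
autoplot.wapls <- function(object, k = object$n_components, ...) {
  df <- tibble::tibble(observed = object$env_t, fitted = object$fitted[, k])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = sprintf("observed env (%s scale)", object$transform),
                  y = "fitted",
                  title = sprintf("WA-PLS component %d (r2 = %.3f)",
                                  k, object$apparent$r2[k]))
}

#' Box plots of isotope values by period
#'
#' The whisker convention matches the box-summary convention of
#' [summarize_by_period()]: boxes span the interquartile range with the
#' median, whiskers span the full minimum-maximum range.
#'
#' @param samples An isotope tibble (see [read_isotopes()]).
#' @param table A [period_table()] used for ordering.
#' @return A ggplot faceted by isotope.
#' @export
plot_isotope_boxes <- function(samples, table = default_period_table()) {
  isos <- intersect(c("d13c", "d15n", "d2h"), names(samples))
  long <- tidyr::pivot_longer(samples, dplyr::all_of(isos),
                              names_to = "isotope", values_to = "delta")
  long <- dplyr::filter(long, !is.na(.data$delta))
  long$period <- factor(long$period, levels = table$label)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$delta)) +
    ggplot2::stat_boxplot(geom = "errorbar", coef = Inf, width = 0.3) +
    ggplot2::geom_boxplot(coef = Inf) +
    ggplot2::facet_wrap(~isotope, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "delta (per mil)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
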