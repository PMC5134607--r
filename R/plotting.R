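# ggplot2 views of each result type.

#' @export
autoplot.gu_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(doy = seq(min(dat$doy), max(dat$doy), by = 0.5))
  grid$gcc <- gu_curve(grid$doy, object$params)
  ggplot2::ggplot(dat, ggplot2::aes(.data$doy, .data$gcc)) +
    ggplot2::geom_point(colour = "grey40", size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "forestgreen", linewidth = 0.8) +
    ggplot2::labs(x = "Day of year", y = "GCC",
                  title = "Gu double-logistic fit") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pheno_ensemble <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$replicates[, c("ud", "sd", "dd", "rd")],
    dplyr::everything(), names_to = "phase", values_to = "doy")
  long$phase <- factor(toupper(long$phase), c("UD", "SD", "DD", "RD"))
  ggplot2::ggplot(long, ggplot2::aes(.data$doy, fill = .data$phase)) +
    ggplot2::geom_histogram(bins = 40, show.legend = FALSE) +
    ggplot2::facet_wrap(~phase, scales = "free_x") +
    ggplot2::labs(x = "Day of year", y = "Replicates",
                  title = "Phenophase uncertainty ensemble") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pheno_map <- function(object,
                               value = c("gsl", "ud", "rd", "range_gcc"),
                               limits = NULL, ...) {
  value <- match.arg(value)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$col, -.data$row, fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = value,
                  title = sprintf("Per-pixel %s map", value)) +
    ggplot2::theme_minimal()
}

#' Fitted-series diagnostic with phenophase lines
#'
#' One panel of the standard processing figure: daily filtered GCC, the
#' fitted curve, and vertical phenophase date lines with their 10th--90th
#' intervals.
#'
#' @param fit A `gu_fit`.
#' @param confidence Output of [phenophase_confidence()].
#' @return A ggplot.
#' @export
plot_phenophases <- function(fit, confidence) {
  p <- autoplot(fit)
  ph <- confidence[confidence$phase %in% c("UD", "SD", "DD", "RD"), ]
  p +
    ggplot2::geom_rect(
      data = ph, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper,
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.15) +
    ggplot2::geom_vline(data = ph,
                        ggplot2::aes(xintercept = .data$median),
                        colour = "steelblue") +
    ggplot2::geom_text(data = ph, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$median, y = Inf,
                                    label = .data$phase),
                       vjust = 1.5, size = 3)
}

#' Raw vs filtered series diagnostic
#'
#' @param raw Sub-daily series before filtering.
#' @param daily Daily series after the filter chain.
#' @return A ggplot.
#' @export
plot_filter_stages <- function(raw, daily) {
  ggplot2::ggplot(raw, ggplot2::aes(.data$doy, .data$gcc)) +
    ggplot2::geom_point(colour = "grey70", size = 0.5) +
    ggplot2::geom_point(data = daily, colour = "black", size = 0.9) +
    ggplot2::labs(x = "Day of year", y = "GCC",
                  title = "Sub-daily raw (grey) and daily filtered (black) GCC") +
    ggplot2::theme_minimal()
}
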