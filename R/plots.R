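# ggplot2 displays for the result types

#' Plot an NND histogram with its CSR reference
#'
#' @param object an [nnd_histogram()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nnd_result <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_col(ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                   y = .data$density),
                      width = df$bin_hi - df$bin_lo,
                      fill = "grey70", color = "grey40") +
    ggplot2::labs(x = "nearest-neighbor distance (nm)", y = "density (1/nm)")
  if (any(is.finite(df$csr_density))) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                   y = .data$csr_density),
      color = "firebrick", linewidth = 0.8)
  }
  p
}

#' Plot a labeling-efficiency fit
#'
#' Objective over the efficiency grid with the minimizer marked.
#'
#' @param object an `le_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.le_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$le, y = .data$objective)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$estimate, color = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "labeling efficiency", y = "sum of squared differences",
                  title = sprintf("estimate = %.2f", object$estimate))
}

#' Plot fitted species fractions
#'
#' @param object a `stoich_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stoich_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$species, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "fraction of complexes")
}

#' Plot a detection-probability scan
#'
#' Detection versus binder off-rate, one panel per imager concentration,
#' colored by binder concentration, line type by mode.
#'
#' @param object a [scan_detection()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$k_off_binder, y = .data$detection,
                               color = factor(.data$c_binder),
                               linetype = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~c_imager, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "binder off-rate (1/s)", y = "detection probability",
                  color = "c_binder (nM)", linetype = NULL)
}

#' @export
plot.nnd_result <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.le_fit <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.stoich_fit <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.scan_result <- function(x, ...) print(autoplot(x, ...))
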