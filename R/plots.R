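#' Footprint size distribution plot
#'
#' Histogram of decoded footprint sizes with the PPP, PIC and nucleosome
#' size windows shaded; the single-molecule analogue of the footprint-size
#' heatmap used to pick classification windows.
#'
#' @param fp footprint tibble.
#' @param max_size truncate the x axis (default 400 bp).
#' @return a ggplot.
#' @export
plot_footprint_sizes <- function(fp, max_size = 400) {
  rules <- classification_rules()
  shade <- tibble(
    lo = c(rules$ppp_size[1], rules$pic_size[1], rules$single_nucleosome[1]),
    hi = c(rules$ppp_size[2], rules$pic_size[2], rules$single_nucleosome[2]),
    class = c("PPP", "PIC", "nucleosome")
  )
  ggplot2::ggplot(filter(fp, .data$size <= max_size)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$class), alpha = 0.15) +
    ggplot2::geom_histogram(ggplot2::aes(x = .data$size), binwidth = 5) +
    ggplot2::labs(x = "footprint size (bp)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn gmm_fit density plot of the fitted mixture over the data.
#' @param object a `gmm_fit`.
#' @export
autoplot.gmm_fit <- function(object, ...) {
  x <- seq(min(object$components$mean - 4 * object$components$sd),
           max(object$components$mean + 4 * object$components$sd),
           length.out = 400)
  dens <- bind_rows(map(seq_len(object$k), function(j) {
    tibble(x = x, component = factor(j),
           density = object$components$weight[j] *
             dnorm(x, object$components$mean[j], object$components$sd[j]))
  }))
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TSS-relative position (bp)", y = "mixture density") +
    ggplot2::theme_minimal()
}

#' Distance-resolved coordination plot
#'
#' Per-bin single-fiber co-occupancy odds ratios with the independence line
#' at OR = 1.
#'
#' @param coord tibble from [global_coordination()] or
#'   [pause_initiation_interference()].
#' @return a ggplot.
#' @export
plot_coordination <- function(coord) {
  coord <- mutate(coord,
                  x = if ("d_lo" %in% names(coord))
                    (.data$d_lo + .data$d_hi) / 2 else as.numeric(factor(.data$bin)))
  ggplot2::ggplot(coord, ggplot2::aes(x = .data$x, y = .data$odds_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance (bp)", y = "co-occupancy odds ratio") +
    ggplot2::theme_minimal()
}
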