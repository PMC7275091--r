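#' Avalanche-size distribution plot
#'
#' Log-log survival-style plot of the empirical size distribution with the
#' fitted truncated power law overlaid on the fit range.
#'
#' @param object an `nc_plfit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nc_plfit <- function(object, ...) {
  tab <- table(object$sizes)
  d <- tibble(s = as.numeric(names(tab)),
              p = as.numeric(tab) / sum(tab))
  sr <- object$s_min:object$s_max
  logq <- -object$alpha_s * log(sr) - sr / object$s_cut
  q <- exp(logq - max(logq))
  in_range <- sum(d$p[d$s >= object$s_min & d$s <= object$s_max])
  fit <- tibble(s = sr, p = q / sum(q) * in_range)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s, y = .data$p)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fit, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "avalanche size s", y = "P(s)",
                  title = sprintf("alpha_s = %.2f, s_cut = %.0f",
                                  object$alpha_s, object$s_cut))
}

#' Raster plot of a spike raster
#'
#' @param object an `nc_raster`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nc_raster <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_ms / 1000, y = .data$unit)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "unit")
}

#' Sweep summary plot
#'
#' Median and 5-95% ribbon of one metric against `K_ext/N`.
#'
#' @param data per-run sweep tibble (e.g. from [run_kext_sweep()]).
#' @param metric unquoted column name.
#' @param N system size (for the `K_ext/N` axis).
#' @return A ggplot.
#' @export
plot_sweep <- function(data, metric, N = 32) {
  agg <- data %>%
    group_by(.data$K_ext) %>%
    summarise(med = median({{ metric }}, na.rm = TRUE),
              lo = quantile({{ metric }}, 0.05, na.rm = TRUE,
                            names = FALSE),
              hi = quantile({{ metric }}, 0.95, na.rm = TRUE,
                            names = FALSE),
              .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$K_ext / N, y = .data$med)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "K_ext / N", y = rlang::as_label(rlang::enquo(metric)))
}

#' PID atom plot
#'
#' @param object an `nc_pid`.
#' @param ... unused.
#' @return A ggplot of the four atoms.
#' @export
autoplot.nc_pid <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$atom, y = .data$bits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "information (bits)")
}
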