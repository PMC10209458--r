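# broom-style accessors and ggplot2 autoplot methods for the result objects.

#' Tidy a monoexponential kinetics fit
#'
#' @param x A [fit_monoexponential()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`A`, `tau`).
#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble(term = c("A", "tau"), estimate = c(x$A, x$tau))
}

#' One-row summary of a monoexponential kinetics fit
#'
#' @param x A [fit_monoexponential()] result.
#' @param ... Unused.
#' @return A one-row tibble: `A`, `tau`, `status`, `rss`, `n`, `window`.
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(A = x$A, tau = x$tau, status = x$status, rss = x$rss, n = x$n,
         window = x$window)
}

#' Plot a kinetics fit over its data
#'
#' @param object A [fit_monoexponential()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  grid <- tibble(t = seq(0, max(object$data$t), length.out = 200))
  grid$value <- object$A * (1 - exp(-grid$t / object$tau))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, color = "red") +
    ggplot2::labs(
      x = "time from window start (s)", y = "normalized ΔF/F0",
      title = sprintf("A = %.3f, tau = %.1f s (%s)", object$A, object$tau,
                      object$status)) +
    ggplot2::theme_minimal()
}

#' Plot a set of ROI intensity traces
#'
#' @param object A `roi_trace_set` (see [extract_roi_traces()] or
#'   [simulate_puncta_timeseries()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roi_trace_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$f,
                                       group = .data$roi)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time (s)", y = "ROI mean intensity") +
    ggplot2::theme_minimal()
}

#' Plot a normalized FRAP trace
#'
#' @param object A [frap_normalize()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_trace <- function(object, ...) {
  bi <- attr(object, "bleach_index")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$f_norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$t[bi], linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(0, 1), color = "grey70") +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot dispersion and recovery series
#'
#' @param object A [dispersion_metrics()] result.
#' @param ... Unused.
#' @return A ggplot of the per-ROI series with the ROI-averaged series
#'   overlaid.
#' @export
autoplot.dispersion_series <- function(object, ...) {
  per_roi <- bind_rows(
    mutate(object$dispersion, phase = "dispersion"),
    mutate(object$recovery, phase = "recovery"))
  mean_s <- bind_rows(
    mutate(object$mean_dispersion, phase = "dispersion"),
    mutate(object$mean_recovery, phase = "recovery"))
  ggplot2::ggplot(per_roi, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$roi), alpha = 0.25) +
    ggplot2::geom_line(data = mean_s, color = "red", linewidth = 1) +
    ggplot2::facet_wrap(~phase, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "ΔF/F0") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a localization table
#'
#' @param locs A localization table.
#' @param color_by Column mapped to color (default `"channel"`).
#' @return A ggplot with equal coordinates in nm.
#' @export
plot_localizations <- function(locs, color_by = "channel") {
  stopifnot(is.data.frame(locs))
  ggplot2::ggplot(locs[locs$accepted, ],
                  ggplot2::aes(x = .data$x_nm, y = .data$y_nm,
                               color = .data[[color_by]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
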