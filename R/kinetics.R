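# Activity-dependent dispersion/recovery statistics and FRAP normalization.
# The normalized dispersion series is dF = (F - F_at_onset) / F0; its value at
# stimulation end gives the mobile fraction; both windows are fitted with the
# monoexponential y = A (1 - exp(-t / tau)).

#' Normalized dispersion and recovery series from ROI traces
#'
#' For each ROI trace F(t): the dispersion series is
#' `(F - F(t_stim)) / F0` over `[t_stim, t_end]` and the recovery series is
#' `(F - F(t_end)) / F0` over `[t_end, t_final]`, so each series is exactly 0
#' at its reference time. `F0` is the mean of all samples before `t_stim`
#' (default) or `F(t_stim)` itself. The mobile fraction is the magnitude of
#' the dispersion series at `t_end`. The per-experiment series is the mean
#' over its ROIs.
#'
#' @param traces A tibble with columns `roi`, `t`, `f` (see
#'   [simulate_puncta_timeseries()] or [extract_roi_traces()]).
#' @param t_stim,t_end,t_final Stimulation onset, stimulation end and trace
#'   end in seconds (defaults 15, 75, 320).
#' @param f0 `"pre_mean"` (default) or `"at_onset"`.
#' @return An object of class `dispersion_series`: tibbles `dispersion` and
#'   `recovery` (`roi`, `t`, `value`), `mobile` (`roi`, `f0`,
#'   `mobile_fraction`), and `mean_dispersion` / `mean_recovery` (ROI-averaged
#'   series, the per-experiment n = 1 unit).
#' @export
dispersion_metrics <- function(traces, t_stim = 15, t_end = 75, t_final = 320,
                               f0 = c("pre_mean", "at_onset")) {
  stopifnot(is.data.frame(traces), all(c("roi", "t", "f") %in% names(traces)))
  f0 <- match.arg(f0)
  if (max(traces$t) < t_final) {
    abort("Traces do not cover the full analysis window [0, t_final].")
  }
  per_roi <- function(df) {
    df <- df[order(df$t), , drop = FALSE]
    f_on <- approx(df$t, df$f, xout = t_stim, rule = 2)$y
    f_end <- approx(df$t, df$f, xout = t_end, rule = 2)$y
    f0v <- if (f0 == "pre_mean") mean(df$f[df$t < t_stim]) else f_on
    if (!is.finite(f0v) || f0v <= 0) {
      abort("Baseline F0 is not positive; cannot normalize the trace.")
    }
    disp <- df[df$t >= t_stim & df$t <= t_end, , drop = FALSE]
    rec <- df[df$t >= t_end & df$t <= t_final, , drop = FALSE]
    list(
      dispersion = tibble(roi = df$roi[1], t = disp$t,
                          value = (disp$f - f_on) / f0v),
      recovery = tibble(roi = df$roi[1], t = rec$t,
                        value = (rec$f - f_end) / f0v),
      mobile = tibble(roi = df$roi[1], f0 = f0v,
                      mobile_fraction = abs((f_end - f_on) / f0v))
    )
  }
  parts <- traces |>
    dplyr::group_split(.data$roi) |>
    purrr::map(per_roi)
  dispersion <- bind_rows(purrr::map(parts, "dispersion"))
  recovery <- bind_rows(purrr::map(parts, "recovery"))
  mobile <- bind_rows(purrr::map(parts, "mobile"))
  mean_series <- function(s) {
    s |>
      group_by(.data$t) |>
      summarise(value = mean(.data$value), .groups = "drop")
  }
  structure(
    list(dispersion = dispersion, recovery = recovery, mobile = mobile,
         mean_dispersion = mean_series(dispersion),
         mean_recovery = mean_series(recovery),
         params = list(t_stim = t_stim, t_end = t_end, t_final = t_final,
                       f0 = f0)),
    class = "dispersion_series"
  )
}

#' Fit a monoexponential y = A (1 - exp(-t / tau)) to a series
#'
#' Bounded Levenberg-Marquardt least squares with time re-zeroed to the window
#' start. Initialization: `A0` is the series endpoint; `tau0` is the time of
#' the first crossing of `(1 - 1/e) * A0` (window/3 as fallback); tau is
#' bounded in `(0, 10 * window]`. A fitted time constant exceeding the window
#' length cannot be resolved within the imaging time and the fit is flagged
#' `excluded`.
#'
#' @param series Tibble with columns `t` and `value` (one series).
#' @param window Window length in seconds (default: span of `t`).
#' @return An object of class `kinetics_fit` with elements `A`, `tau`,
#'   `status` (`"converged"` or `"excluded"`), `rss`, `n`, `window`, `data`.
#' @export
fit_monoexponential <- function(series, window = NULL) {
  stopifnot(is.data.frame(series), all(c("t", "value") %in% names(series)))
  if (any(!is.finite(series$t)) || any(!is.finite(series$value))) {
    abort("Series contains non-finite values.")
  }
  series <- series[order(series$t), , drop = FALSE]
  t0 <- series$t - series$t[1]
  window <- window %||% max(t0)
  if (sum(t0 <= window) < 5) abort("Need at least 5 points inside the window.")
  keep <- t0 <= window
  tt <- t0[keep]; yy <- series$value[keep]
  A0 <- yy[length(yy)]
  if (A0 == 0) A0 <- if (max(abs(yy)) > 0) yy[which.max(abs(yy))] else 1e-6
  cross <- which(abs(yy) >= (1 - exp(-1)) * abs(A0))[1]
  tau0 <- if (!is.na(cross) && tt[cross] > 0) tt[cross] else window / 3
  fit <- minpack.lm::nls.lm(
    par = c(A = A0, tau = tau0),
    lower = c(-Inf, 1e-9), upper = c(Inf, 10 * window),
    fn = function(p) yy - p[1] * (1 - exp(-tt / p[2])),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  A <- unname(fit$par[1]); tau <- unname(fit$par[2])
  status <- if (tau > window) "excluded" else "converged"
  structure(
    list(A = A, tau = tau, status = status, rss = sum(fit$fvec^2),
         n = length(yy), window = window,
         data = tibble(t = tt, value = yy)),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> A = %.4g, tau = %.4g s (%s; n = %d, window = %g s)\n",
              x$A, x$tau, x$status, x$n, x$window))
  invisible(x)
}

#' Normalize a FRAP trace to its pre- and post-bleach points
#'
#' Affine map sending the pre-bleach mean to 1 and the bleach-point value to
#' 0; the normalized trace is invariant under any positive affine transform of
#' the raw intensities.
#'
#' @param trace Tibble with columns `t`, `f`.
#' @param bleach_index Index of the first post-bleach sample (default: the
#'   trace's `bleach_index` attribute, else the index of the minimum).
#' @param pre_window Indices of the pre-bleach samples (default: everything
#'   before `bleach_index`).
#' @return A tibble of class `frap_trace` with columns `t`, `f`,
#'   `f_norm`.
#' @export
frap_normalize <- function(trace, bleach_index = NULL, pre_window = NULL) {
  stopifnot(is.data.frame(trace), all(c("t", "f") %in% names(trace)))
  bleach_index <- bleach_index %||% attr(trace, "bleach_index") %||%
    which.min(trace$f)
  if (bleach_index < 2) abort("`bleach_index` must leave a pre-bleach window.")
  pre_window <- pre_window %||% seq_len(bleach_index - 1L)
  pre <- mean(trace$f[pre_window])
  fb <- trace$f[bleach_index]
  if (pre == fb) abort("Degenerate normalization: pre-bleach mean equals the bleach-point value.")
  out <- tibble(t = trace$t, f = trace$f,
                f_norm = (trace$f - fb) / (pre - fb))
  attr(out, "bleach_index") <- bleach_index
  class(out) <- c("frap_trace", class(out))
  out
}

#' Fit FRAP recovery and report the mobile fraction
#'
#' Fits the monoexponential recovery on the normalized post-bleach series;
#' the plateau `A` of the fit is the mobile fraction estimate (pre-bleach = 1,
#' bleach point = 0 by construction of [frap_normalize()]).
#'
#' @param frap A [frap_normalize()] result.
#' @return A `kinetics_fit` whose `A` estimates the mobile fraction.
#' @export
frap_fit <- function(frap) {
  stopifnot(inherits(frap, "frap_trace"))
  bi <- attr(frap, "bleach_index")
  post <- frap[seq(bi, nrow(frap)), , drop = FALSE]
  fit_monoexponential(tibble(t = post$t, value = post$f_norm))
}
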