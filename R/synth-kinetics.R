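# Synthetic condensate kinetics: activity-dependent puncta dispersion /
# recovery time series and FRAP traces with known generating parameters.

#' Ground-truth parameters for an activity-dependent dispersion experiment
#'
#' The noiseless punctum intensity follows a piecewise monoexponential model:
#' baseline before stimulation onset, dispersion
#' \eqn{F(t) = F_0 [1 - A (1 - e^{-(t - t_{on})/\tau_d})]} during stimulation,
#' and recovery back toward baseline with time constant `tau_recovery`
#' afterwards. The mobile fraction implied by the model is the magnitude of
#' the normalized drop at stimulation end,
#' \eqn{A (1 - e^{-(t_{end}-t_{on})/\tau_d})}.
#'
#' @param f0 Baseline fluorescence (arbitrary units, default 1).
#' @param amplitude Dispersion amplitude `A` (dimensionless).
#' @param tau_dispersion Dispersion time constant, s.
#' @param tau_recovery Recovery time constant, s.
#' @param recovery_fraction Fraction of the dispersed signal that returns
#'   (default 1, full reassembly).
#' @param stim_onset,stim_end,trace_end Stimulation window and trace end, s
#'   (defaults 15, 75, 320).
#' @param dt Sampling interval, s (default 5, i.e. 0.2 Hz).
#' @param noise_sd Gaussian noise SD on the normalized trace (default 0).
#' @return An object of class `kinetics_truth`.
#' @export
kinetics_truth <- function(f0 = 1, amplitude = 0.36, tau_dispersion = 23.5,
                           tau_recovery = 106, recovery_fraction = 1,
                           stim_onset = 15, stim_end = 75, trace_end = 320,
                           dt = 5, noise_sd = 0) {
  check_scalar(f0, "f0", positive = TRUE)
  check_scalar(amplitude, "amplitude")
  check_scalar(tau_dispersion, "tau_dispersion", positive = TRUE)
  check_scalar(tau_recovery, "tau_recovery", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!(stim_onset < stim_end && stim_end < trace_end)) {
    abort("Windows must satisfy stim_onset < stim_end < trace_end.")
  }
  if (recovery_fraction < 0 || recovery_fraction > 1) {
    abort("`recovery_fraction` must be in [0, 1].")
  }
  mobile <- abs(amplitude) * (1 - exp(-(stim_end - stim_onset) / tau_dispersion))
  structure(
    list(f0 = f0, amplitude = amplitude, tau_dispersion = tau_dispersion,
         tau_recovery = tau_recovery, recovery_fraction = recovery_fraction,
         stim_onset = stim_onset, stim_end = stim_end, trace_end = trace_end,
         dt = dt, noise_sd = noise_sd, mobile_fraction = mobile),
    class = "kinetics_truth"
  )
}

# Noiseless model trace at times t (same units as the truth windows).
kinetics_model_trace <- function(kin, t) {
  A <- kin$amplitude
  drop_end <- A * (1 - exp(-(kin$stim_end - kin$stim_onset) / kin$tau_dispersion))
  f <- numeric(length(t))
  pre <- t <= kin$stim_onset
  dis <- t > kin$stim_onset & t <= kin$stim_end
  rec <- t > kin$stim_end
  f[pre] <- 1
  f[dis] <- 1 - A * (1 - exp(-(t[dis] - kin$stim_onset) / kin$tau_dispersion))
  f[rec] <- (1 - drop_end) + kin$recovery_fraction * drop_end *
    (1 - exp(-(t[rec] - kin$stim_end) / kin$tau_recovery))
  kin$f0 * f
}

#' Simulate puncta intensity time series with known kinetics
#'
#' @param kin A [kinetics_truth()].
#' @param n_puncta Number of ROI traces to generate.
#' @param seed Integer seed.
#' @return A tibble of class `roi_trace_set` with columns `roi`, `t`, `f`,
#'   carrying the generating truth in `attr(, "truth")`.
#' @export
simulate_puncta_timeseries <- function(kin, n_puncta = 10, seed = 1) {
  stopifnot(inherits(kin, "kinetics_truth"))
  t <- seq(0, kin$trace_end, by = kin$dt)
  base <- kinetics_model_trace(kin, t)
  withr::with_seed(seed, {
    traces <- purrr::map(seq_len(n_puncta), function(i) {
      noise <- if (kin$noise_sd > 0) rnorm(length(t), 0, kin$noise_sd * kin$f0) else 0
      tibble(roi = i, t = t, f = base + noise)
    })
  })
  out <- bind_rows(traces)
  attr(out, "truth") <- kin
  class(out) <- c("roi_trace_set", class(out))
  out
}

#' Ground-truth parameters for a FRAP experiment
#'
#' Pre-bleach plateau, instantaneous bleach to `bleach_depth`, then
#' monoexponential recovery toward
#' `pre_bleach * mobile_fraction + bleach_depth * (1 - mobile_fraction)`.
#'
#' @param pre_bleach Pre-bleach intensity (default 1).
#' @param bleach_depth Intensity immediately after the bleach (default 0).
#' @param bleach_time Time of the bleach, s; must be at or after the second
#'   sample so a pre-bleach window exists.
#' @param mobile_fraction Fraction of recoverable signal, in `[0, 1]`.
#' @param tau_recovery Recovery time constant, s.
#' @param trace_end Trace end, s.
#' @param dt Sampling interval, s (default 5).
#' @param noise_sd Gaussian noise SD (default 0).
#' @return An object of class `frap_truth`.
#' @export
frap_truth <- function(pre_bleach = 1, bleach_depth = 0, bleach_time = 30,
                       mobile_fraction = 1, tau_recovery = 20,
                       trace_end = 300, dt = 5, noise_sd = 0) {
  check_scalar(pre_bleach, "pre_bleach", positive = TRUE)
  check_scalar(tau_recovery, "tau_recovery", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    abort("`mobile_fraction` must be in [0, 1].")
  }
  if (bleach_depth < 0 || bleach_depth >= pre_bleach) {
    abort("`bleach_depth` must be in [0, pre_bleach).")
  }
  if (bleach_time < dt) {
    abort("`bleach_time` must not precede the first post-start sample.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(pre_bleach = pre_bleach, bleach_depth = bleach_depth,
         bleach_time = bleach_time, mobile_fraction = mobile_fraction,
         tau_recovery = tau_recovery, trace_end = trace_end, dt = dt,
         noise_sd = noise_sd),
    class = "frap_truth"
  )
}

#' Simulate a FRAP trace with known truth
#'
#' @param kin A [frap_truth()].
#' @param seed Integer seed.
#' @return A tibble with columns `t`, `f`; the bleach frame index is stored in
#'   `attr(, "bleach_index")` and the truth in `attr(, "truth")`.
#' @export
simulate_frap_trace <- function(kin, seed = 1) {
  stopifnot(inherits(kin, "frap_truth"))
  t <- seq(0, kin$trace_end, by = kin$dt)
  bleach_index <- which(t >= kin$bleach_time)[1]
  plateau <- kin$pre_bleach * kin$mobile_fraction +
    kin$bleach_depth * (1 - kin$mobile_fraction)
  f <- numeric(length(t))
  pre <- seq_len(bleach_index - 1L)
  f[pre] <- kin$pre_bleach
  post <- bleach_index:length(t)
  f[post] <- kin$bleach_depth + (plateau - kin$bleach_depth) *
    (1 - exp(-(t[post] - t[bleach_index]) / kin$tau_recovery))
  if (kin$noise_sd > 0) {
    withr::with_seed(seed, {
      f <- f + rnorm(length(f), 0, kin$noise_sd * kin$pre_bleach)
    })
  }
  out <- tibble(t = t, f = f)
  attr(out, "bleach_index") <- bleach_index
  attr(out, "truth") <- kin
  out
}
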