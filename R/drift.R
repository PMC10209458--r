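# Fiducial-based drift estimation and correction. Bright stationary beads are
# tracked across frames; their smoothed mean displacement relative to the
# first frame is subtracted from every localization.

#' Estimate sample drift from fiducial localizations
#'
#' For each fiducial seed position, the accepted localization nearest the seed
#' (within `search_radius`) is taken as that fiducial's position in each
#' frame. Displacements are measured relative to the fiducial's position in
#' the first frame where it is seen, averaged over fiducials, interpolated
#' across frames where a fiducial is missing, and smoothed with a centered
#' moving average whose window shrinks symmetrically at the trace ends (so a
#' linear drift is recovered without endpoint bias). The returned trace is
#' re-anchored so that frame 1 has zero displacement.
#'
#' @param locs A localization table (see [localize_stack()]).
#' @param fiducials Tibble of seed positions with columns `x_nm`, `y_nm`.
#' @param n_frames Total number of frames the trace must cover (default: max
#'   frame present).
#' @param search_radius Match radius around the seed, nm (default 500).
#' @param smooth_window Moving-average window, frames (default 100).
#' @param min_coverage Minimum fraction of frames in which a fiducial must be
#'   found (default 0.9); fiducials below it are dropped with a warning.
#' @return A `drift_trace` tibble with columns `frame`, `dx`, `dy`, `dz` (nm).
#' @export
estimate_drift <- function(locs, fiducials, n_frames = NULL,
                           search_radius = 500, smooth_window = 100,
                           min_coverage = 0.9) {
  stopifnot(is.data.frame(locs), is.data.frame(fiducials),
            all(c("x_nm", "y_nm") %in% names(fiducials)))
  n_frames <- n_frames %||% max(locs$frame)
  ok <- locs[locs$accepted, , drop = FALSE]
  per_fid <- vector("list", nrow(fiducials))
  for (i in seq_len(nrow(fiducials))) {
    d2 <- (ok$x_nm - fiducials$x_nm[i])^2 + (ok$y_nm - fiducials$y_nm[i])^2
    near <- ok[d2 <= search_radius^2, , drop = FALSE]
    if (nrow(near) == 0) next
    # one record per frame: the brightest match
    near <- near[order(near$frame, -near$amplitude), , drop = FALSE]
    near <- near[!duplicated(near$frame), , drop = FALSE]
    if (nrow(near) < min_coverage * n_frames) {
      warn(sprintf("Fiducial %d visible in only %d/%d frames; dropped.",
                   i, nrow(near), n_frames))
      next
    }
    zf <- if (all(is.na(near$z_nm))) rep(0, nrow(near)) else near$z_nm
    zf[is.na(zf)] <- 0
    fr <- seq_len(n_frames)
    ix <- approx(near$frame, near$x_nm, xout = fr, rule = 2)$y
    iy <- approx(near$frame, near$y_nm, xout = fr, rule = 2)$y
    iz <- approx(near$frame, zf, xout = fr, rule = 2)$y
    per_fid[[i]] <- cbind(ix - ix[1], iy - iy[1], iz - iz[1])
  }
  per_fid <- per_fid[!vapply(per_fid, is.null, logical(1))]
  if (length(per_fid) == 0) {
    abort("No fiducial could be tracked: drift estimation impossible. Check fiducial seed positions and detection settings.")
  }
  mean_disp <- Reduce(`+`, per_fid) / length(per_fid)
  sm <- apply(mean_disp, 2, moving_average_centered, window = smooth_window)
  sm <- sweep(sm, 2, sm[1, ])
  out <- tibble(frame = seq_len(n_frames),
                dx = sm[, 1], dy = sm[, 2], dz = sm[, 3])
  class(out) <- c("drift_trace", class(out))
  out
}

#' Subtract a drift trace from a localization table
#'
#' @param locs A localization table.
#' @param trace A [estimate_drift()] result covering every frame in `locs`.
#' @return The corrected table; `attr(, "drift_corrected")` is set.
#' @export
apply_drift_correction <- function(locs, trace) {
  stopifnot(is.data.frame(locs), is.data.frame(trace),
            all(c("frame", "dx", "dy", "dz") %in% names(trace)))
  if (!all(locs$frame %in% trace$frame)) {
    abort("Drift trace does not cover every frame present in the table.")
  }
  idx <- match(locs$frame, trace$frame)
  locs$x_nm <- locs$x_nm - trace$dx[idx]
  locs$y_nm <- locs$y_nm - trace$dy[idx]
  if ("z_nm" %in% names(locs)) locs$z_nm <- locs$z_nm - trace$dz[idx]
  attr(locs, "drift_corrected") <- TRUE
  locs
}
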