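#' Quality-filter a localization table
#'
#' Removes records that fail any bound; per-criterion removal counts are
#' reported with a message. Non-accepted fits are always removed.
#'
#' @param locs A localization table.
#' @param width_range `c(min, max)` bounds on both fitted widths, nm.
#' @param amplitude_min Minimum fitted photon count.
#' @param amplitude_max Maximum fitted photon count (default `Inf`). A finite
#'   ceiling near 1.5x the single-emitter photon budget rejects fits of two
#'   emitters active simultaneously in the same diffraction-limited spot,
#'   whose merged image fits as a single Gaussian with roughly double the
#'   photon count.
#' @param residual_max Maximum normalized fit residual.
#' @param quiet Suppress the per-criterion message (default FALSE).
#' @return The filtered table.
#' @export
filter_localizations <- function(locs, width_range = c(50, 1000),
                                 amplitude_min = 0, amplitude_max = Inf,
                                 residual_max = Inf, quiet = FALSE) {
  stopifnot(is.data.frame(locs))
  if (width_range[2] <= width_range[1]) {
    abort("`width_range` bounds are inverted.")
  }
  n0 <- nrow(locs)
  fail_acc <- !locs$accepted
  fail_w <- !fail_acc & (locs$wx_nm < width_range[1] | locs$wx_nm > width_range[2] |
                           locs$wy_nm < width_range[1] | locs$wy_nm > width_range[2])
  if (amplitude_max <= amplitude_min) abort("Amplitude bounds are inverted.")
  fail_a <- !fail_acc & !fail_w & (locs$amplitude < amplitude_min |
                                     locs$amplitude > amplitude_max)
  fail_r <- !fail_acc & !fail_w & !fail_a & locs$residual > residual_max
  keep <- !(fail_acc | fail_w | fail_a | fail_r)
  out <- locs[keep, , drop = FALSE]
  if (!quiet) {
    inform(sprintf(
      "filter_localizations: kept %d/%d (removed: %d rejected fits, %d width, %d amplitude, %d residual)",
      nrow(out), n0, sum(fail_acc), sum(fail_w), sum(fail_a), sum(fail_r)))
  }
  if (nrow(out) == 0) warn("All localizations removed by the filters.")
  out
}
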