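# Single-molecule localization: frame smoothing, candidate detection, and
# least-squares fitting of a pixel-integrated elliptical 2D Gaussian. The
# fitted x/y widths feed the astigmatism-based z assignment.

#' Smooth a raw frame before spot detection
#'
#' 2D Gaussian filter with a mass-normalized kernel; the filter "radius"
#' follows the convention sigma = radius / 2. `radius = 0` is the identity.
#'
#' @param frame Numeric matrix of camera counts.
#' @param radius Filter radius in pixels (default 1).
#' @return A matrix of the same shape.
#' @export
preprocess_frame <- function(frame, radius = 1) {
  stopifnot(is.matrix(frame))
  if (radius < 0) abort("`radius` must be >= 0.")
  gaussian_smooth(frame, sigma = radius / 2)
}

#' Detect candidate spots in a smoothed frame
#'
#' Candidates are local maxima (8-neighborhood) exceeding
#' `mean(frame) + k_sigma * sd(frame)`, kept in decreasing order of intensity
#' with a minimum Chebyshev separation of `min_sep` pixels. Ties between equal
#' maxima are broken toward the smaller row-major index.
#'
#' @param frame Smoothed frame (matrix).
#' @param k_sigma Detection threshold in SD units above the frame mean
#'   (default 4).
#' @param min_sep Minimum separation between candidates, pixels (default 3,
#'   one fit-window radius).
#' @return A tibble with columns `row`, `col`, `value`; possibly zero rows.
#' @export
detect_candidates <- function(frame, k_sigma = 4, min_sep = 3) {
  stopifnot(is.matrix(frame))
  thr <- mean(frame) + k_sigma * sd(frame)
  if (!is.finite(thr)) return(tibble(row = integer(), col = integer(), value = numeric()))
  nr <- nrow(frame); nc <- ncol(frame)
  cand <- which(frame > thr)
  if (length(cand) == 0) {
    return(tibble(row = integer(), col = integer(), value = numeric()))
  }
  rr <- ((cand - 1L) %% nr) + 1L
  cc <- ((cand - 1L) %/% nr) + 1L
  is_max <- vapply(seq_along(cand), function(i) {
    r <- rr[i]; c <- cc[i]
    nb_r <- max(1L, r - 1L):min(nr, r + 1L)
    nb_c <- max(1L, c - 1L):min(nc, c + 1L)
    v <- frame[r, c]
    nb <- frame[nb_r, nb_c]
    if (any(nb > v)) return(FALSE)
    # tie-break: among equal neighbors keep only the smallest row-major index
    eq <- which(nb == v, arr.ind = TRUE)
    idx <- (nb_c[eq[, 2]] - 1L) * nr + nb_r[eq[, 1]]
    min(idx) == (c - 1L) * nr + r
  }, logical(1))
  rr <- rr[is_max]; cc <- cc[is_max]
  vv <- frame[cbind(rr, cc)]
  ord <- order(-vv, (cc - 1L) * nr + rr)
  keep_r <- integer(); keep_c <- integer()
  for (i in ord) {
    if (length(keep_r) == 0 ||
        all(pmax(abs(keep_r - rr[i]), abs(keep_c - cc[i])) >= min_sep)) {
      keep_r <- c(keep_r, rr[i]); keep_c <- c(keep_c, cc[i])
    }
  }
  tibble(row = keep_r, col = keep_c, value = frame[cbind(keep_r, keep_c)])
}

# Pixel-integrated elliptical Gaussian model on a window; par = (x, y, wx, wy,
# photons, offset) in pixel units except photons/offset in counts.
spot_model <- function(par, rows, cols) {
  fx <- pnorm((cols - par[1]) / par[3]) - pnorm((cols - 1 - par[1]) / par[3])
  fy <- pnorm((rows - par[2]) / par[4]) - pnorm((rows - 1 - par[2]) / par[4])
  par[6] + par[5] * outer(fy, fx)
}

#' Fit a single spot with a pixel-integrated elliptical 2D Gaussian
#'
#' Levenberg-Marquardt least squares of an axis-aligned elliptical Gaussian
#' (integrated over pixels) plus a constant offset, on a square window
#' centered on the candidate pixel. Candidates whose window is clipped by the
#' frame edge are skipped (`NULL`). Fits failing quality checks (amplitude,
#' center inside the window, widths away from the optimizer bounds) are
#' returned with `accepted = FALSE`.
#'
#' @param frame Raw frame (matrix of counts).
#' @param row,col Candidate pixel (1-based).
#' @param window Window side in pixels, odd (default 7).
#' @param pixel_size Pixel size in nm (default 200).
#' @param amplitude_min Minimum fitted photon count to accept (default 100).
#' @return A one-row tibble (`x_nm`, `y_nm`, `wx_nm`, `wy_nm`, `amplitude`,
#'   `offset`, `residual`, `accepted`) or `NULL` when the window is clipped.
#' @export
fit_spot_2d <- function(frame, row, col, window = 7, pixel_size = 200,
                        amplitude_min = 100) {
  stopifnot(is.matrix(frame), window %% 2 == 1)
  half <- (window - 1L) / 2L
  if (row - half < 1 || row + half > nrow(frame) ||
      col - half < 1 || col + half > ncol(frame)) {
    return(NULL)
  }
  rows <- (row - half):(row + half)
  cols <- (col - half):(col + half)
  w <- frame[rows, cols]
  off0 <- min(w)
  tot <- sum(w - off0)
  if (tot <= 0) {
    return(tibble(x_nm = NA_real_, y_nm = NA_real_, wx_nm = NA_real_,
                  wy_nm = NA_real_, amplitude = 0, offset = off0,
                  residual = Inf, accepted = FALSE))
  }
  wc <- pmax(w - off0, 0)
  cx <- sum(t(wc) * (cols - 0.5)) / sum(wc)
  cy <- sum(wc * (rows - 0.5)) / sum(wc)
  sx0 <- sqrt(max(sum(t(wc) * (cols - 0.5 - cx)^2) / sum(wc), 0.1))
  sy0 <- sqrt(max(sum(wc * (rows - 0.5 - cy)^2) / sum(wc), 0.1))
  par0 <- c(cx, cy, sx0, sy0, tot, off0)
  lower <- c(cols[1] - 1, rows[1] - 1, 0.25, 0.25, 0, -Inf)
  upper <- c(cols[window], rows[window], 10, 10, Inf, Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0,
      lower = lower, upper = upper,
      fn = function(p) as.numeric(w - spot_model(p, rows, cols)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble(x_nm = NA_real_, y_nm = NA_real_, wx_nm = NA_real_,
                  wy_nm = NA_real_, amplitude = NA_real_, offset = NA_real_,
                  residual = Inf, accepted = FALSE))
  }
  p <- fit$par
  rss <- sum(fit$fvec^2)
  denom <- sum((w - mean(w))^2)
  residual <- if (denom > 0) rss / denom else Inf
  accepted <- p[5] >= amplitude_min &&
    p[1] > cols[1] - 1 && p[1] < cols[window] &&
    p[2] > rows[1] - 1 && p[2] < rows[window] &&
    p[3] > 0.26 && p[3] < 9.9 && p[4] > 0.26 && p[4] < 9.9
  tibble(
    x_nm = p[1] * pixel_size, y_nm = p[2] * pixel_size,
    wx_nm = p[3] * pixel_size, wy_nm = p[4] * pixel_size,
    amplitude = p[5], offset = p[6], residual = residual,
    accepted = accepted
  )
}

#' Localize every frame of a blinking movie
#'
#' Runs smoothing, candidate detection and spot fitting on each frame, and,
#' when a calibration is supplied, assigns z from the fitted width difference.
#' Localizations inherit the frame's scheduled channel label.
#'
#' @param stack A [frame_stack()].
#' @param calibration Optional [fit_astigmatism_calibration()] result; without
#'   it `z_nm` is `NA`.
#' @param k_sigma Candidate detection threshold (default 4).
#' @param window Fit window side, pixels (default 7).
#' @param smooth_radius Pre-detection smoothing radius, pixels (default 1).
#' @param amplitude_min Minimum accepted photon count (default 100).
#' @return A `localization_table` tibble with columns `frame`, `channel`,
#'   `x_nm`, `y_nm`, `z_nm`, `wx_nm`, `wy_nm`, `amplitude`, `offset`,
#'   `residual`, `accepted`. `attr(, "pixel_size")` records the scale.
#' @export
localize_stack <- function(stack, calibration = NULL, k_sigma = 4, window = 7,
                           smooth_radius = 1, amplitude_min = 100) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$pixels)[3]
  px <- stack$pixel_size
  out <- vector("list", n)
  for (f in seq_len(n)) {
    frame <- stack$pixels[, , f]
    sm <- preprocess_frame(frame, radius = smooth_radius)
    cand <- detect_candidates(sm, k_sigma = k_sigma,
                              min_sep = (window - 1) / 2)
    if (nrow(cand) == 0) next
    fits <- purrr::pmap(list(cand$row, cand$col), function(r, c) {
      fit_spot_2d(frame, r, c, window = window, pixel_size = px,
                  amplitude_min = amplitude_min)
    })
    fits <- bind_rows(fits[!vapply(fits, is.null, logical(1))])
    if (nrow(fits) == 0) next
    fits$frame <- f
    fits$channel <- stack$channel_schedule[f]
    out[[f]] <- fits
  }
  locs <- bind_rows(out)
  if (nrow(locs) == 0) {
    locs <- tibble(frame = integer(), channel = character(), x_nm = numeric(),
                   y_nm = numeric(), wx_nm = numeric(), wy_nm = numeric(),
                   amplitude = numeric(), offset = numeric(),
                   residual = numeric(), accepted = logical())
  }
  locs$z_nm <- NA_real_
  if (!is.null(calibration) && nrow(locs) > 0) {
    locs$z_nm <- assign_z(locs$wx_nm, locs$wy_nm, calibration)
  }
  locs <- locs[, c("frame", "channel", "x_nm", "y_nm", "z_nm", "wx_nm",
                   "wy_nm", "amplitude", "offset", "residual", "accepted")]
  attr(locs, "pixel_size") <- px
  class(locs) <- c("localization_table", class(locs))
  locs
}
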