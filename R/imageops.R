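# Time-lapse and fixed-image operations: rolling-ball background subtraction,
# translation-only registration, circular-ROI traces, coefficient-of-variation
# line scans, droplet line profiles and 2D droplet colocalization.

as_stack <- function(x) {
  if (inherits(x, "frame_stack")) return(x$pixels)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  abort("Expected a matrix, a rows x cols x frames array, or a frame_stack.")
}

#' Rolling-ball background subtraction
#'
#' Estimates the per-frame background as the grayscale morphological opening
#' of the image with a disc structuring element of the given radius (the
#' envelope of a ball rolled under the intensity surface) and subtracts it.
#' The output is non-negative by construction. A radius at least as large as
#' the image yields a constant background equal to the image minimum, with a
#' warning.
#'
#' @param x Matrix, `rows x cols x frames` array, or [frame_stack()].
#' @param radius Ball radius in pixels (default 50).
#' @return The background-corrected object, same shape/class as the input.
#' @export
rolling_ball_background <- function(x, radius = 50) {
  check_scalar(radius, "radius", positive = TRUE)
  pixels <- as_stack(x)
  d <- dim(pixels)
  if (2 * radius + 1 >= min(d[1], d[2])) {
    warn("Rolling-ball radius >= image size; using the global minimum plane as background.")
    bg_fun <- function(fr) matrix(min(fr), d[1], d[2])
  } else {
    brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
    bg_fun <- function(fr) {
      # EBImage grayscale morphology works on [0, 1] intensities; opening is
      # positively homogeneous, so rescale, open, scale back
      m <- max(abs(fr), 1e-12)
      EBImage::opening(fr / m, brush) * m
    }
  }
  out <- pixels
  for (f in seq_len(d[3])) {
    fr <- pixels[, , f]
    out[, , f] <- pmax(fr - bg_fun(fr), 0)
  }
  if (inherits(x, "frame_stack")) {
    x$pixels <- out
    return(x)
  }
  if (is.matrix(x)) return(out[, , 1]) else return(out)
}

# Cross-correlation translation between two frames via FFT, with parabolic
# subpixel refinement. Returns c(dy, dx): the shift that maps `ref` onto `fr`.
xcorr_shift <- function(ref, fr) {
  if (sd(fr) == 0 || sd(ref) == 0) return(c(0, 0))
  cc <- Re(fft(fft(ref) * Conj(fft(fr)), inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  n <- dim(cc)
  wrap <- function(i, nn) ifelse(i - 1 > nn / 2, i - 1 - nn, i - 1)
  sub <- function(ax) {
    i <- peak[ax]
    im <- ifelse(i == 1, n[ax], i - 1)
    ip <- ifelse(i == n[ax], 1, i + 1)
    pick <- function(j) if (ax == 1) cc[j, peak[2]] else cc[peak[1], j]
    c0 <- pick(i); cm <- pick(im); cp <- pick(ip)
    den <- 2 * c0 - cm - cp
    if (den <= 0) 0 else (cp - cm) / (2 * den)
  }
  s <- -(c(wrap(peak[1], n[1]) + sub(1), wrap(peak[2], n[2]) + sub(2)))
  s[abs(s) < 1e-6] <- 0
  s
}

# Bilinear translation of a frame by (dy, dx) pixels (content moves by -shift
# to align onto the reference); out-of-field pixels are edge-replicated.
translate_bilinear <- function(fr, dy, dx) {
  nr <- nrow(fr); nc <- ncol(fr)
  ry <- seq_len(nr) + dy
  rx <- seq_len(nc) + dx
  y0 <- pmin(pmax(floor(ry), 1), nr); y1 <- pmin(y0 + 1, nr)
  x0 <- pmin(pmax(floor(rx), 1), nc); x1 <- pmin(x0 + 1, nc)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- fr[y0, x0, drop = FALSE]; b <- fr[y0, x1, drop = FALSE]
  c2 <- fr[y1, x0, drop = FALSE]; d2 <- fr[y1, x1, drop = FALSE]
  wa <- outer(1 - fy, 1 - fx); wb <- outer(1 - fy, fx)
  wc <- outer(fy, 1 - fx); wd <- outer(fy, fx)
  a * wa + b * wb + c2 * wc + d2 * wd
}

#' Register a time-lapse stack by translation
#'
#' Each frame is aligned to the first frame by maximizing the FFT
#' cross-correlation, with parabolic subpixel refinement; frames are
#' resampled bilinearly. Featureless frames (flat similarity surface) get a
#' zero shift with a warning.
#'
#' @param x `rows x cols x frames` array or [frame_stack()].
#' @return A list with `stack` (aligned, same class as input) and `shifts`
#'   (tibble `frame`, `dx_px`, `dy_px`: the estimated displacement of each
#'   frame relative to frame 1).
#' @export
register_timelapse <- function(x) {
  pixels <- as_stack(x)
  d <- dim(pixels)
  if (d[3] < 2) abort("Registration needs at least 2 frames.")
  ref <- pixels[, , 1]
  flat_warned <- FALSE
  shifts <- matrix(0, d[3], 2)
  out <- pixels
  for (f in 2:d[3]) {
    fr <- pixels[, , f]
    if (sd(fr) == 0 || sd(ref) == 0) {
      if (!flat_warned) {
        warn("Featureless frame(s): similarity surface is flat; zero shift assumed.")
        flat_warned <- TRUE
      }
      next
    }
    s <- xcorr_shift(ref, fr)
    shifts[f, ] <- s
    out[, , f] <- translate_bilinear(fr, s[1], s[2])
  }
  shift_tbl <- tibble(frame = seq_len(d[3]),
                      dy_px = shifts[, 1], dx_px = shifts[, 2])
  if (inherits(x, "frame_stack")) {
    x$pixels <- out
    return(list(stack = x, shifts = shift_tbl))
  }
  list(stack = out, shifts = shift_tbl)
}

# Pixels whose centers lie within `radius_px` of (x_px, y_px); pixel (r, c)
# center is at (c - 0.5, r - 0.5) in pixel units.
disk_pixels <- function(x_px, y_px, radius_px, nr, nc) {
  cols <- max(1, floor(x_px - radius_px)):min(nc, ceiling(x_px + radius_px) + 1)
  rows <- max(1, floor(y_px - radius_px)):min(nr, ceiling(y_px + radius_px) + 1)
  grid <- expand.grid(row = rows, col = cols)
  d2 <- (grid$col - 0.5 - x_px)^2 + (grid$row - 0.5 - y_px)^2
  grid[d2 <= radius_px^2, , drop = FALSE]
}

#' Extract circular-ROI mean-intensity traces from a stack
#'
#' The ROI disk is the set of pixels whose centers lie within `diameter / 2`
#' of the ROI center; the trace is the per-frame mean over the disk. ROIs
#' clipped by the frame border are an error.
#'
#' @param x `rows x cols x frames` array or [frame_stack()].
#' @param centers Tibble with columns `roi`, `x_px`, `y_px` (pixel units).
#' @param diameter_um ROI diameter in micrometers (default 1.08).
#' @param pixel_size_nm Pixel size in nm (default: the stack's, else 200).
#' @param dt Sampling interval in seconds (default 5, i.e. 0.2 Hz).
#' @return A tibble of class `roi_trace_set` with columns `roi`, `t`, `f`.
#' @export
extract_roi_traces <- function(x, centers, diameter_um = 1.08,
                               pixel_size_nm = NULL, dt = 5) {
  pixels <- as_stack(x)
  pixel_size_nm <- pixel_size_nm %||%
    (if (inherits(x, "frame_stack")) x$pixel_size else 200)
  stopifnot(is.data.frame(centers),
            all(c("roi", "x_px", "y_px") %in% names(centers)))
  d <- dim(pixels)
  radius_px <- diameter_um * 1000 / 2 / pixel_size_nm
  traces <- purrr::pmap(
    list(centers$roi, centers$x_px, centers$y_px),
    function(roi, x_px, y_px) {
      if (x_px - radius_px < 0 || x_px + radius_px > d[2] ||
          y_px - radius_px < 0 || y_px + radius_px > d[1]) {
        abort(sprintf("ROI '%s' is clipped by the frame border.", roi))
      }
      disk <- disk_pixels(x_px, y_px, radius_px, d[1], d[2])
      idx <- cbind(disk$row, disk$col)
      f <- vapply(seq_len(d[3]),
                  function(fr) mean(pixels[, , fr][idx]), numeric(1))
      tibble(roi = roi, t = (seq_len(d[3]) - 1) * dt, f = f)
    })
  out <- bind_rows(traces)
  attr(out, "centers") <- centers
  attr(out, "dt") <- dt
  class(out) <- c("roi_trace_set", class(out))
  out
}

# Nearest-pixel samples of a band of the given width along a polyline:
# unit steps along each segment, integer perpendicular offsets.
sample_polyline_band <- function(image, polyline, width) {
  stopifnot(is.matrix(image), is.data.frame(polyline),
            all(c("x_px", "y_px") %in% names(polyline)), nrow(polyline) >= 2)
  half <- floor(width / 2)
  offs <- -half:half
  vals <- list()
  for (s in seq_len(nrow(polyline) - 1)) {
    p <- c(polyline$x_px[s], polyline$y_px[s])
    q <- c(polyline$x_px[s + 1], polyline$y_px[s + 1])
    L <- sqrt(sum((q - p)^2))
    if (L == 0) next
    dir <- (q - p) / L
    nrm <- c(-dir[2], dir[1])
    ts <- seq(0, L, by = 1)
    pts_x <- rep(p[1] + ts * dir[1], each = length(offs)) +
      rep(offs * nrm[1], times = length(ts))
    pts_y <- rep(p[2] + ts * dir[2], each = length(offs)) +
      rep(offs * nrm[2], times = length(ts))
    col <- floor(pts_x) + 1L
    row <- floor(pts_y) + 1L
    if (any(col < 1 | col > ncol(image) | row < 1 | row > nrow(image))) {
      abort("Polyline band extends outside the image.")
    }
    vals[[s]] <- image[cbind(row, col)]
  }
  unlist(vals)
}

#' Coefficient of variation along a line scan
#'
#' Samples a band of the given width along the polyline (unit steps, integer
#' perpendicular offsets, nearest-pixel lookup) and reports the mean, standard
#' deviation and their ratio CV = SD / mean — the dispersion metric for
#' punctate versus diffuse fluorescence along an axon. Optional rolling-ball
#' and Gaussian preprocessing can be applied first (as in the fixed-image
#' dispersion analysis); they are off by default.
#'
#' @param image Numeric matrix.
#' @param polyline Tibble with columns `x_px`, `y_px` (at least two vertices).
#' @param width Band width in pixels (default 5).
#' @param rolling_ball_radius Optional rolling-ball radius (default `NULL`,
#'   off).
#' @param smooth_sigma Optional Gaussian sigma in pixels (default `NULL`,
#'   off; the fixed-image analysis uses 1.0).
#' @return A one-row tibble with `mean`, `sd`, `cv`, `n_samples`.
#' @export
cv_along_line <- function(image, polyline, width = 5,
                          rolling_ball_radius = NULL, smooth_sigma = NULL) {
  stopifnot(is.matrix(image))
  if (!is.null(rolling_ball_radius)) {
    image <- rolling_ball_background(image, rolling_ball_radius)
  }
  if (!is.null(smooth_sigma)) image <- gaussian_smooth(image, smooth_sigma)
  v <- sample_polyline_band(image, polyline, width)
  m <- mean(v)
  if (m == 0) abort("Zero mean luminance along the line; CV undefined.")
  tibble(mean = m, sd = sd(v), cv = sd(v) / m, n_samples = length(v))
}

#' Normalize CVs against a control group
#'
#' @param cv Numeric vector of CVs.
#' @param control_cv Numeric vector of control-group CVs.
#' @return `cv / mean(control_cv)`.
#' @export
normalize_cv <- function(cv, control_cv) {
  m <- mean(control_cv)
  if (!is.finite(m) || m <= 0) abort("Control CV mean must be positive.")
  cv / m
}

#' Intensity profile along a straight line, normalized to its maximum
#'
#' Nearest-pixel sampling at unit steps along the line (averaged across the
#' band when `width > 1`); intensities are divided by the profile maximum so
#' the brightest position maps to exactly 1.
#'
#' @param image Numeric matrix.
#' @param line Tibble with two rows and columns `x_px`, `y_px`.
#' @param width Band width in pixels (default 1).
#' @return A tibble with `distance_px`, `intensity`, `intensity_norm`.
#' @export
line_scan_profile <- function(image, line, width = 1) {
  stopifnot(is.matrix(image), nrow(line) == 2)
  p <- c(line$x_px[1], line$y_px[1]); q <- c(line$x_px[2], line$y_px[2])
  L <- sqrt(sum((q - p)^2))
  if (L == 0) abort("Line has zero length.")
  dir <- (q - p) / L
  nrm <- c(-dir[2], dir[1])
  half <- floor(width / 2)
  ts <- seq(0, L, by = 1)
  intensity <- vapply(ts, function(s) {
    pts_x <- p[1] + s * dir[1] + (-half:half) * nrm[1]
    pts_y <- p[2] + s * dir[2] + (-half:half) * nrm[2]
    col <- floor(pts_x) + 1L; row <- floor(pts_y) + 1L
    if (any(col < 1 | col > ncol(image) | row < 1 | row > nrow(image))) {
      abort("Line extends outside the image.")
    }
    mean(image[cbind(row, col)])
  }, numeric(1))
  mx <- max(intensity)
  if (mx <= 0) abort("All-zero profile; normalization undefined.")
  tibble(distance_px = ts, intensity = intensity, intensity_norm = intensity / mx)
}

#' Two-channel 2D droplet colocalization
#'
#' Per channel: rolling-ball background subtraction, Gaussian smoothing
#' (sigma = 1 by default), Otsu binarization; then directional pixel-overlap
#' Manders coefficients between the two droplet masks.
#'
#' @param image_a,image_b Co-registered numeric matrices of the same shape.
#' @param rolling_ball_radius Rolling-ball radius, pixels (default 50).
#' @param smooth_sigma Gaussian sigma, pixels (default 1).
#' @return A list with `metrics` (one-row tibble `manders_a_in_b`,
#'   `manders_b_in_a`, `pixels_a`, `pixels_b`, `overlap_pixels`) and the
#'   binary `mask_a`, `mask_b`.
#' @export
droplet_colocalization_2d <- function(image_a, image_b,
                                      rolling_ball_radius = 50,
                                      smooth_sigma = 1) {
  stopifnot(is.matrix(image_a), is.matrix(image_b))
  if (!identical(dim(image_a), dim(image_b))) {
    abort("Channel images must have the same shape.")
  }
  seg <- function(img) {
    if (max(img) == min(img)) {
      abort("Constant channel: Otsu binarization undefined.")
    }
    img <- rolling_ball_background(img, rolling_ball_radius)
    img <- gaussian_smooth(img, smooth_sigma)
    if (max(img) == min(img)) {
      abort("Constant channel after preprocessing: Otsu binarization undefined.")
    }
    img > otsu_threshold(img)
  }
  mask_a <- seg(image_a); mask_b <- seg(image_b)
  na <- sum(mask_a); nb <- sum(mask_b); nov <- sum(mask_a & mask_b)
  if (na == 0 || nb == 0) abort("Empty droplet mask after binarization.")
  list(
    metrics = tibble(manders_a_in_b = nov / na, manders_b_in_a = nov / nb,
                     pixels_a = na, pixels_b = nb, overlap_pixels = nov),
    mask_a = mask_a, mask_b = mask_b
  )
}
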