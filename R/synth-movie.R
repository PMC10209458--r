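# Synthetic single-molecule blinking movies: sparse emitters drawn inside the
# ground-truth cluster of the frame's scheduled activation channel, rendered
# with a pixel-integrated astigmatic Gaussian PSF, plus stationary bright
# fiducial beads, lateral/axial drift and Poisson shot noise.

#' Acquisition specification for a synthetic blinking movie
#'
#' @param n_frames Number of frames.
#' @param frame_size `c(rows, cols)` in pixels (default `c(128, 128)`).
#' @param channels Channel labels cycled over frames (default alternating
#'   `"A"`, `"B"`, mimicking alternating-activation two-color acquisition).
#' @param drift `NULL` (no drift) or a function `frame -> c(dx, dy, dz)` nm,
#'   with `drift(1) == c(0, 0, 0)`. See [linear_drift()].
#' @param fiducials `NULL` or a tibble with columns `x_nm`, `y_nm`,
#'   `photons`; fiducials are rendered in every frame, at focus, and should be
#'   much brighter than single emitters.
#' @param emitters_per_frame Mean number of activated emitters per frame
#'   (Poisson).
#' @param frame_rate Frames per second (default 100).
#' @param seed Integer seed; the same spec and seed reproduce the movie
#'   bit-exactly.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_frames, frame_size = c(128, 128),
                             channels = c("A", "B"), drift = NULL,
                             fiducials = NULL, emitters_per_frame = 5,
                             frame_rate = 100, seed = 1) {
  check_scalar(n_frames, "n_frames", positive = TRUE)
  stopifnot(length(frame_size) == 2L, all(frame_size >= 8))
  if (!is.null(drift) && !is.function(drift)) {
    abort("`drift` must be NULL or a function frame -> c(dx, dy, dz) in nm.")
  }
  if (!is.null(fiducials)) {
    stopifnot(is.data.frame(fiducials),
              all(c("x_nm", "y_nm", "photons") %in% names(fiducials)))
    fiducials <- as_tibble(fiducials)
  }
  check_scalar(emitters_per_frame, "emitters_per_frame")
  schedule <- rep_len(channels, n_frames)
  structure(
    list(n_frames = as.integer(n_frames), frame_size = as.integer(frame_size),
         channel_schedule = schedule, drift = drift, fiducials = fiducials,
         emitters_per_frame = emitters_per_frame,
         frame_rate = frame_rate, seed = as.integer(seed)),
    class = "acquisition_spec"
  )
}

#' Linear drift trajectory
#'
#' @param rate `c(dx, dy, dz)` drift per frame in nm.
#' @return A function `frame -> c(dx, dy, dz)` with zero displacement at
#'   frame 1.
#' @export
linear_drift <- function(rate) {
  rate <- rep_len(as.numeric(rate), 3L)
  function(frame) outer(frame - 1, rate)
}

#' Construct a frame stack
#'
#' A multi-frame image container: a `rows x cols x frames` numeric array of
#' 16-bit camera counts plus acquisition metadata.
#'
#' @param pixels 3D array `rows x cols x frames`.
#' @param pixel_size Pixel size in nm.
#' @param frame_rate Frames per second.
#' @param channel_schedule Per-frame channel label.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(pixels, pixel_size = 200, frame_rate = 100,
                        channel_schedule = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  n <- dim(pixels)[3]
  if (is.null(channel_schedule)) channel_schedule <- rep("A", n)
  if (length(channel_schedule) != n) {
    abort("`channel_schedule` length must equal the number of frames.")
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size, frame_rate = frame_rate,
         channel_schedule = as.character(channel_schedule)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%g nm/px), channels: %s\n",
              d[3], d[1], d[2], x$pixel_size,
              paste(unique(x$channel_schedule), collapse = "/")))
  invisible(x)
}

# Render one pixel-integrated Gaussian spot into a frame (in place-ish).
# x,y in nm with pixel (r, c) spanning x in [(c-1)*px, c*px), y likewise.
add_spot <- function(frame, x, y, wx, wy, photons, px) {
  nr <- nrow(frame); nc <- ncol(frame)
  half <- ceiling(4 * max(wx, wy) / px)
  c0 <- floor(x / px) + 1; r0 <- floor(y / px) + 1
  cols <- max(1, c0 - half):min(nc, c0 + half)
  rows <- max(1, r0 - half):min(nr, r0 + half)
  if (length(cols) == 0 || length(rows) == 0) return(frame)
  fx <- pnorm((cols * px - x) / wx) - pnorm(((cols - 1) * px - x) / wx)
  fy <- pnorm((rows * px - y) / wy) - pnorm(((rows - 1) * px - y) / wy)
  frame[rows, cols] <- frame[rows, cols] + photons * outer(fy, fx)
  frame
}

#' Simulate a two-channel single-molecule blinking movie
#'
#' Per frame, a Poisson number of emitters is activated uniformly inside the
#' ground-truth cluster of the frame's scheduled channel; each is rendered as
#' a pixel-integrated elliptical Gaussian whose x/y widths encode its axial
#' position through the optics model's astigmatism curves. Stationary
#' fiducial beads (at focus) are rendered in every frame. Drift displaces
#' emitters and fiducials alike; the truth table records positions before
#' drift. Pixel values are Poisson draws around PSF sum plus background
#' (unless `optics$noise_model == "none"`), clamped to the 16-bit camera
#' range.
#'
#' @param truth A [generate_ground_truth_synapse()] result. Its masks are
#'   positioned in the camera field by `offset_nm`.
#' @param optics An [optics_model()].
#' @param acq An [acquisition_spec()].
#' @param offset_nm `c(x, y)` nm position of the truth-volume origin in the
#'   camera field (default centers the volume).
#' @return A list with `stack` (a [frame_stack()]), `truth_locs` (tibble of
#'   true emitter records: `frame`, `channel`, `x_nm`, `y_nm`, `z_nm`,
#'   pre-drift), `drift_truth` (per-frame `dx`, `dy`, `dz`), and `offset_nm`.
#' @export
simulate_blinking_movie <- function(truth, optics, acq, offset_nm = NULL) {
  stopifnot(inherits(truth, "ground_truth_synapse"),
            inherits(optics, "optics_model"),
            inherits(acq, "acquisition_spec"))
  px <- optics$pixel_size
  nr <- acq$frame_size[1]; nc <- acq$frame_size[2]
  dims <- dim(truth$mask_a)
  extent <- dims * truth$voxel_edge
  if (is.null(offset_nm)) {
    offset_nm <- c((nc * px - extent[1]) / 2, (nr * px - extent[2]) / 2)
  }
  if (any(offset_nm < 0) || offset_nm[1] + extent[1] > nc * px ||
      offset_nm[2] + extent[2] > nr * px) {
    abort("Truth volume does not fit inside the camera field at this offset.")
  }
  max_z <- truth$origin[3] + extent[3]
  if (max(abs(truth$origin[3]), abs(max_z)) > optics$z_range) {
    abort("Truth volume exceeds the optics z validity range.")
  }
  w_max <- max(psf_widths(optics, c(-1, 1) * optics$z_range * 0.75)$wx)
  spot_area <- (6 * w_max / px)^2
  if (acq$emitters_per_frame * spot_area > 0.2 * nr * nc) {
    warn("Emitter rate high enough that spots will frequently overlap; single-emitter fitting assumptions are violated.")
  }

  vox_idx <- list(
    A = which(truth$mask_a, arr.ind = TRUE),
    B = which(truth$mask_b, arr.ind = TRUE)
  )
  edge <- truth$voxel_edge
  origin <- truth$origin

  drift_fun <- acq$drift %||% function(f) outer(f - 1, c(0, 0, 0)) * 0
  dr <- drift_fun(seq_len(acq$n_frames))
  dr <- matrix(dr, ncol = 3)
  drift_truth <- tibble(frame = seq_len(acq$n_frames),
                        dx = dr[, 1], dy = dr[, 2], dz = dr[, 3])

  withr::with_seed(acq$seed, {
    pixels <- array(0, dim = c(nr, nc, acq$n_frames))
    recs <- vector("list", acq$n_frames)
    for (f in seq_len(acq$n_frames)) {
      ch <- acq$channel_schedule[f]
      frame <- matrix(optics$background_rate, nr, nc)
      n_em <- rpois(1, acq$emitters_per_frame)
      vi <- vox_idx[[ch]]
      if (is.null(vi)) n_em <- 0L
      if (n_em > 0) {
        pick <- vi[sample.int(nrow(vi), n_em, replace = TRUE), , drop = FALSE]
        ex <- origin[1] + (pick[, 1] - 1 + runif(n_em)) * edge + offset_nm[1]
        ey <- origin[2] + (pick[, 2] - 1 + runif(n_em)) * edge + offset_nm[2]
        ez <- origin[3] + (pick[, 3] - 1 + runif(n_em)) * edge
        for (i in seq_len(n_em)) {
          zi <- min(max(ez[i] + dr[f, 3], -optics$z_range), optics$z_range)
          w <- psf_widths(optics, zi)
          frame <- add_spot(frame, ex[i] + dr[f, 1], ey[i] + dr[f, 2],
                            w$wx, w$wy, optics$photons_per_emitter, px)
        }
        recs[[f]] <- tibble(frame = f, channel = ch,
                            x_nm = ex, y_nm = ey, z_nm = ez)
      }
      if (!is.null(acq$fiducials)) {
        zi <- min(max(dr[f, 3], -optics$z_range), optics$z_range)
        wf <- psf_widths(optics, zi)
        for (i in seq_len(nrow(acq$fiducials))) {
          frame <- add_spot(frame,
                            acq$fiducials$x_nm[i] + dr[f, 1],
                            acq$fiducials$y_nm[i] + dr[f, 2],
                            wf$wx, wf$wy, acq$fiducials$photons[i], px)
        }
      }
      if (optics$noise_model == "poisson") {
        frame <- matrix(rpois(length(frame), frame), nr, nc)
        if (optics$read_noise_sd > 0) {
          frame <- frame + round(rnorm(length(frame), 0, optics$read_noise_sd))
        }
        frame <- pmax(frame, 0)
      }
      pixels[, , f] <- pmin(frame, 65535)
    }
    truth_locs <- bind_rows(recs)
  })
  list(
    stack = frame_stack(pixels, pixel_size = px, frame_rate = acq$frame_rate,
                        channel_schedule = acq$channel_schedule),
    truth_locs = truth_locs,
    drift_truth = drift_truth,
    offset_nm = offset_nm
  )
}

#' Simulate an astigmatism calibration stack
#'
#' Evaluates the optics model's width curves on a regular z grid, emulating a
#' bead z-stack used to calibrate the width-difference-to-z mapping.
#'
#' @param optics An [optics_model()].
#' @param z_range Half-range of the scan in nm (default the optics validity
#'   range). Must not exceed the optics validity range.
#' @param z_step Step in nm (default 10; must be > 0).
#' @param width_noise_sd Optional Gaussian noise on the widths, nm.
#' @param seed Seed used when `width_noise_sd > 0`.
#' @return A tibble with columns `z`, `wx`, `wy`, ordered in `z`.
#' @export
simulate_calibration_stack <- function(optics, z_range = optics$z_range,
                                       z_step = 10, width_noise_sd = 0,
                                       seed = 1) {
  stopifnot(inherits(optics, "optics_model"))
  check_scalar(z_step, "z_step", positive = TRUE)
  if (z_range > optics$z_range) {
    abort("`z_range` exceeds the validity range of the optics model.")
  }
  z <- seq(-z_range, z_range, by = z_step)
  out <- psf_widths(optics, z)
  if (width_noise_sd > 0) {
    withr::with_seed(seed, {
      out$wx <- out$wx + rnorm(nrow(out), 0, width_noise_sd)
      out$wy <- out$wy + rnorm(nrow(out), 0, width_noise_sd)
    })
  }
  out
}
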