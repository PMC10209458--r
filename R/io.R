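# File formats: multi-page 16-bit TIFF for frame stacks (bit-exact round
# trip), CSV for localization tables, YAML for run configuration. Every image
# written gets a YAML sidecar carrying the acquisition metadata.

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' Pixel values must be integers in `[0, 65535]`; they survive a round trip
#' bit-exactly. Metadata (pixel size, frame rate, channel schedule) is written
#' to a `<path>.yaml` sidecar.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- stack$pixels
  if (any(px < 0) || any(px > 65535) || any(px != round(px))) {
    abort("Frame stack pixels must be integers in [0, 65535] for 16-bit TIFF.")
  }
  pages <- purrr::map(seq_len(dim(px)[3]), function(f) px[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(
    list(pixel_size = stack$pixel_size, frame_rate = stack$frame_rate,
         channel_schedule = as.list(stack$channel_schedule)),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page 16-bit TIFF as a frame stack
#'
#' Pixel values are preserved bit-exactly. Metadata is taken from the
#' `<path>.yaml` sidecar when present, otherwise defaults are used with a
#' message.
#'
#' @param path TIFF path.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      abort(sprintf("Failed to parse TIFF '%s': %s", path,
                                    conditionMessage(e)))
                    })
  if (!is.list(pages)) pages <- list(pages)
  dims <- purrr::map(pages, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1) {
    bad <- which(purrr::map_chr(dims, paste, collapse = "x") !=
                   paste(dims[[1]], collapse = "x"))[1]
    abort(sprintf("Non-uniform page shapes in '%s' (page %d differs).", path, bad))
  }
  pixels <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    frame_stack(pixels, pixel_size = meta$pixel_size,
                frame_rate = meta$frame_rate,
                channel_schedule = unlist(meta$channel_schedule))
  } else {
    inform("No metadata sidecar found; using defaults (200 nm/px, 100 Hz, single channel).")
    frame_stack(pixels)
  }
}

loc_required_cols <- c("frame", "channel", "x_nm", "y_nm")
loc_standard_cols <- c("frame", "channel", "x_nm", "y_nm", "z_nm", "wx_nm",
                       "wy_nm", "amplitude", "offset", "residual", "accepted")

#' Write a localization table as CSV
#'
#' @param locs A localization table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(locs, path) {
  stopifnot(is.data.frame(locs))
  missing <- setdiff(loc_required_cols, names(locs))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_csv(locs, path)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Columns may appear in any order; unknown columns are preserved. Missing
#' required columns or non-numeric coordinates are errors naming the column
#' and the first offending row.
#'
#' @param path CSV path.
#' @return A `localization_table` tibble.
#' @export
read_localization_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  locs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(loc_required_cols, names(locs))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in intersect(c("x_nm", "y_nm", "z_nm", "wx_nm", "wy_nm",
                          "amplitude", "offset", "residual"), names(locs))) {
    v <- locs[[col]]
    if (!is.numeric(v) && !is.logical(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(coerced))[1]
      abort(sprintf("Non-numeric value in column '%s' at data row %d.", col, bad))
    }
  }
  if (is.character(locs$frame)) abort("Non-numeric value in column 'frame'.")
  class(locs) <- c("localization_table", class(locs))
  locs
}

#' Read and validate a run configuration
#'
#' YAML mapping with explicit defaults mirroring the analysis constants
#' (200 nm pixels, 10 nm voxels, smoothing radii 1 px / 2 voxels / sigma 1.0,
#' rolling-ball radius 50 px, ROI diameter 1.08 um, analysis windows
#' 15-75 s and 75-320 s, 26-connectivity). Unknown keys are rejected.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    abort("`path` must be a YAML file path or a named list.")
  }
  defaults <- list(
    seed = 1L,
    out_dir = ".",
    stages = list("storm", "kinetics"),
    storm = list(
      n_frames = 600L, frame_size = c(64L, 64L), emitters_per_frame = 1,
      overlap = 0.5, com_offset = 50, radius_a = 150,
      pixel_size = 200, voxel_edge = 10,
      photons_per_emitter = 3000, background_rate = 10,
      drift_per_frame = c(0, 0, 0), fiducial_photons = 10000,
      smooth_radius_px = 1, filter_radius_vox = 2, connectivity = 26L,
      k_sigma = 4, fit_window_px = 7L
    ),
    kinetics = list(
      n_traces = 10L, amplitude = 0.36, tau_dispersion = 23.5,
      tau_recovery = 106, noise_sd = 0.02,
      t_stim = 15, t_end = 75, t_final = 320, dt = 5
    )
  )
  merge_cfg <- function(def, got, where) {
    extra <- setdiff(names(got), names(def))
    if (length(extra) > 0) {
      abort(sprintf("Unknown config key(s) %s in %s.",
                    paste(extra, collapse = ", "), where))
    }
    for (k in names(got)) {
      def[[k]] <- if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        merge_cfg(def[[k]], got[[k]], paste0(where, "$", k))
      } else {
        got[[k]]
      }
    }
    def
  }
  cfg <- merge_cfg(defaults, cfg, "config")
  cfg$stages <- unlist(cfg$stages)
  bad <- setdiff(cfg$stages, c("storm", "kinetics"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  with(cfg$storm, {
    if (any(c(pixel_size, voxel_edge, photons_per_emitter) <= 0)) {
      abort("Lengths and photon counts in the config must be positive.")
    }
  })
  with(cfg$kinetics, {
    if (!(t_stim < t_end && t_end < t_final)) {
      abort("Kinetics windows must satisfy t_stim < t_end < t_final.")
    }
  })
  structure(cfg, class = c("run_config", "list"))
}
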