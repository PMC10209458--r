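#' Optical model for astigmatic single-molecule imaging
#'
#' Describes the microscope used to form single-molecule images: camera pixel
#' size, the in-focus PSF width, and the astigmatism introduced by a
#' cylindrical lens, which makes the fitted Gaussian widths in x and y diverge
#' with defocus in opposite directions. Widths follow a quadratic defocus
#' curve with opposite-sign focal offsets,
#' \deqn{w_x(z) = w_0 + a (z + \gamma)^2, \quad w_y(z) = w_0 + a (z - \gamma)^2,}
#' so the width difference \eqn{w_x - w_y = 4 a \gamma z} is linear
#' (hence strictly monotone) in z and analytically invertible, and
#' \eqn{w_x(0) = w_y(0)}.
#'
#' @param pixel_size Camera pixel size in nm (default 200).
#' @param psf_sigma_focus In-focus Gaussian PSF sigma `w0`, nm (default 180).
#' @param focal_offset Astigmatic focal offset `gamma`, nm (default 350).
#' @param defocus_curvature Quadratic defocus coefficient `a`, 1/nm
#'   (default 6e-4). Together with `focal_offset` this sets the
#'   width-difference slope `4 a gamma` (about 0.84 nm of width difference
#'   per nm of z), a typical operating point giving ~10 nm axial precision
#'   at the default photon budget.
#' @param z_range Validity half-range of the model in z, nm (default 400).
#' @param photons_per_emitter Photons collected per emitter per frame
#'   (default 3000).
#' @param background_rate Mean background, photons/pixel/frame (default 10).
#' @param noise_model `"poisson"` (default) or `"none"` (noise-free frames,
#'   useful for exact checks).
#' @param read_noise_sd Standard deviation of additive Gaussian read noise in
#'   counts (default 0, i.e. pure Poisson).
#' @return An object of class `optics_model`.
#' @examples
#' om <- optics_model()
#' psf_widths(om, z = c(-300, 0, 300))
#' @export
optics_model <- function(pixel_size = 200,
                         psf_sigma_focus = 180,
                         focal_offset = 350,
                         defocus_curvature = 6e-4,
                         z_range = 400,
                         photons_per_emitter = 3000,
                         background_rate = 10,
                         noise_model = c("poisson", "none"),
                         read_noise_sd = 0) {
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(psf_sigma_focus, "psf_sigma_focus", positive = TRUE)
  check_scalar(focal_offset, "focal_offset", positive = TRUE)
  check_scalar(defocus_curvature, "defocus_curvature", positive = TRUE)
  check_scalar(z_range, "z_range", positive = TRUE)
  check_scalar(photons_per_emitter, "photons_per_emitter", positive = TRUE)
  check_scalar(background_rate, "background_rate")
  if (background_rate < 0) abort("`background_rate` must be >= 0.")
  check_scalar(read_noise_sd, "read_noise_sd")
  if (read_noise_sd < 0) abort("`read_noise_sd` must be >= 0.")
  structure(
    list(
      pixel_size = pixel_size,
      psf_sigma_focus = psf_sigma_focus,
      focal_offset = focal_offset,
      defocus_curvature = defocus_curvature,
      z_range = z_range,
      photons_per_emitter = photons_per_emitter,
      background_rate = background_rate,
      noise_model = match.arg(noise_model),
      read_noise_sd = read_noise_sd
    ),
    class = "optics_model"
  )
}

#' PSF widths of an optics model at given axial positions
#'
#' @param optics An [optics_model()].
#' @param z Axial positions in nm.
#' @return A tibble with columns `z`, `wx`, `wy` (nm).
#' @export
psf_widths <- function(optics, z) {
  stopifnot(inherits(optics, "optics_model"))
  if (any(abs(z) > optics$z_range)) {
    abort("`z` outside the validity range of the optics model.")
  }
  tibble(
    z = as.numeric(z),
    wx = optics$psf_sigma_focus +
      optics$defocus_curvature * (z + optics$focal_offset)^2,
    wy = optics$psf_sigma_focus +
      optics$defocus_curvature * (z - optics$focal_offset)^2
  )
}

# Analytic inverse of the width-difference curve; used as an oracle and to
# position the calibration validity range. d = wx - wy = 4*a*gamma*z.
z_from_width_diff <- function(optics, d) {
  d / (4 * optics$defocus_curvature * optics$focal_offset)
}

#' @export
print.optics_model <- function(x, ...) {
  cat("<optics_model>\n")
  cat(sprintf("  pixel size        : %g nm\n", x$pixel_size))
  cat(sprintf("  PSF sigma (focus) : %g nm\n", x$psf_sigma_focus))
  cat(sprintf("  astigmatism       : gamma %g nm, curvature %g /nm\n",
              x$focal_offset, x$defocus_curvature))
  cat(sprintf("  z validity        : +/- %g nm\n", x$z_range))
  cat(sprintf("  photons/emitter   : %g, background %g /px/frame, noise %s\n",
              x$photons_per_emitter, x$background_rate, x$noise_model))
  invisible(x)
}
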