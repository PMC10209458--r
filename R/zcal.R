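# Astigmatism z-calibration: the difference of the fitted x and y Gaussian
# widths maps monotonically to axial position; the calibration interpolates
# that mapping from a measured bead z-stack.

#' Fit an astigmatism z-calibration from a calibration table
#'
#' Builds a monotone piecewise-linear interpolant from the width difference
#' `d = wx - wy` to `z`, from ordered `(z, wx, wy)` calibration rows. The
#' interpolant reproduces the node z values exactly; its validity range is the
#' range of `d` over the nodes.
#'
#' @param table A data frame with numeric columns `z`, `wx`, `wy`, at least 5
#'   rows, `z` strictly increasing and `wx - wy` strictly monotone.
#' @return An object of class `astig_calibration`.
#' @export
fit_astigmatism_calibration <- function(table) {
  stopifnot(is.data.frame(table), all(c("z", "wx", "wy") %in% names(table)))
  if (nrow(table) < 5) abort("Calibration needs at least 5 (z, wx, wy) nodes.")
  if (any(diff(table$z) <= 0)) abort("Calibration `z` must be strictly increasing.")
  d <- table$wx - table$wy
  dd <- diff(d)
  if (!(all(dd > 0) || all(dd < 0))) {
    abort("Width difference wx - wy is not strictly monotone; calibration unusable.")
  }
  structure(
    list(nodes = tibble(z = table$z, wx = table$wx, wy = table$wy, d = d),
         map = approxfun(d, table$z, rule = 1),
         valid_range = range(d)),
    class = "astig_calibration"
  )
}

#' Assign axial positions from fitted spot widths
#'
#' Maps the fitted width difference `wx - wy` through the calibration's
#' monotone interpolant. Differences outside the calibrated range yield `NA`
#' (the localization is excluded from 3D analysis).
#'
#' @param wx,wy Fitted widths in nm (vectors).
#' @param calibration An [fit_astigmatism_calibration()] result.
#' @return A numeric vector of z in nm, `NA` where out of range.
#' @export
assign_z <- function(wx, wy, calibration) {
  stopifnot(inherits(calibration, "astig_calibration"))
  calibration$map(wx - wy)
}

#' @export
print.astig_calibration <- function(x, ...) {
  cat(sprintf("<astig_calibration> %d nodes, z in [%g, %g] nm, wx-wy in [%g, %g] nm\n",
              nrow(x$nodes), min(x$nodes$z), max(x$nodes$z),
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}
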