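# Shared numeric helpers: separable Gaussian smoothing, Otsu thresholding,
# centered moving averages. These are deliberately small and convention-free so
# the imaging modules can share one definition of each primitive.

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

# Band matrix realizing 1D convolution with replicate (clamp-to-edge) padding,
# so constant signals are exactly preserved.
conv_matrix <- function(n, kernel) {
  half <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in seq_along(kernel)) {
    off <- o - half - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + kernel[o]
  }
  K
}

#' Smooth a 2D or 3D array with an isotropic Gaussian filter
#'
#' Separable convolution with a normalized Gaussian kernel truncated at four
#' standard deviations, using replicate padding at the borders (a constant
#' input is returned unchanged). `sigma = 0` is the identity.
#'
#' @param x A numeric matrix or 3D array.
#' @param sigma Standard deviation of the Gaussian, in pixels/voxels.
#' @return An object of the same shape as `x`.
#' @export
gaussian_smooth <- function(x, sigma) {
  stopifnot(is.numeric(x))
  if (sigma <= 0) return(x)
  k <- gaussian_kernel_1d(sigma)
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    K1 <- conv_matrix(nrow(x), k)
    K2 <- conv_matrix(ncol(x), k)
    return(K1 %*% x %*% t(K2))
  }
  if (length(d) == 3L) {
    out <- x
    for (ax in 1:3) {
      K <- conv_matrix(d[ax], k)
      perm <- c(ax, setdiff(1:3, ax))
      m <- matrix(aperm(out, perm), nrow = d[ax])
      m <- K %*% m
      out <- aperm(array(m, d[perm]), order(perm))
    }
    return(out)
  }
  abort("gaussian_smooth() supports 2D matrices and 3D arrays only.")
}

#' Otsu threshold of a numeric array
#'
#' Classic between-class-variance maximization on a fixed-bin histogram over
#' the data range. The threshold is invariant under positive affine rescaling
#' of the input (the histogram bins rescale with the data). Ties are broken
#' toward the lowest qualifying threshold, deterministically.
#'
#' @param x Numeric vector or array.
#' @param nbins Number of histogram bins (default 256).
#' @return The threshold value; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  v <- as.numeric(x)
  rng <- range(v)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    abort("Otsu threshold undefined: input is constant.")
  }
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  t_idx <- which.max(sigma_b) # first maximum: lowest threshold wins ties
  breaks[t_idx + 1]
}

# Centered moving average whose window shrinks symmetrically near the ends,
# so a linear trend is reproduced without endpoint bias.
moving_average_centered <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  k <- pmin(half, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - k
  hi <- seq_len(n) + k
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}
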