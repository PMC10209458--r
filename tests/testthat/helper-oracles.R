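# Independent brute-force oracles used across the suite. These deliberately
# use naive enumeration / direct formulas, never the implementation path.

# Dense 2D convolution with a normalized Gaussian kernel and replicate
# padding, written as an explicit quadruple loop over kernel taps.
oracle_gaussian_conv2d <- function(x, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  taps <- seq(-half, half)
  k <- dnorm(taps, sd = sigma)
  k <- k / sum(k)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      acc <- 0
      for (a in seq_along(taps)) {
        for (b in seq_along(taps)) {
          ii <- min(max(i + taps[a], 1L), nrow(x))
          jj <- min(max(j + taps[b], 1L), ncol(x))
          acc <- acc + k[a] * k[b] * x[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Exhaustive local-maximum scan: pixels strictly above threshold that are >=
# every 8-neighbor.
oracle_local_maxima <- function(x, thr) {
  hits <- NULL
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      if (x[i, j] <= thr) next
      nb <- x[max(1, i - 1):min(nrow(x), i + 1),
              max(1, j - 1):min(ncol(x), j + 1)]
      if (all(x[i, j] >= nb)) hits <- rbind(hits, c(i, j))
    }
  }
  hits
}

# Brute-force grayscale opening with a disc: min then max over enumerated
# in-disc offsets (edge pixels use the available support).
oracle_disc_opening <- function(x, radius) {
  offs <- subset(expand.grid(di = -radius:radius, dj = -radius:radius),
                 di^2 + dj^2 <= radius^2)
  stage <- function(img, fun) {
    out <- img
    for (i in seq_len(nrow(img))) {
      for (j in seq_len(ncol(img))) {
        ii <- i + offs$di; jj <- j + offs$dj
        ok <- ii >= 1 & ii <= nrow(img) & jj >= 1 & jj <= ncol(img)
        out[i, j] <- fun(img[cbind(ii[ok], jj[ok])])
      }
    }
    out
  }
  stage(stage(x, min), max)
}

# Flood-fill connected-component labeling of a logical 3D array.
oracle_label_3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, dim = d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      i <- ((v - 1) %% d[1]) + 1
      j <- (((v - 1) %/% d[1]) %% d[2]) + 1
      k <- ((v - 1) %/% (d[1] * d[2])) + 1
      for (o in seq_len(nrow(offs))) {
        ni <- i + offs[o, 1]; nj <- j + offs[o, 2]; nk <- k + offs[o, 3]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
        nv <- (nk - 1) * d[1] * d[2] + (nj - 1) * d[1] + ni
        if (mask[nv] && lab[nv] == 0L) {
          lab[nv] <- cur
          queue <- c(queue, nv)
        }
      }
    }
  }
  lab
}

# Render one noiseless pixel-integrated Gaussian spot on an otherwise flat
# frame (direct formula; mirrors the physics, not the package internals).
oracle_spot_frame <- function(nr, nc, x_px, y_px, sx_px, sy_px, photons,
                              offset = 0) {
  fx <- pnorm((seq_len(nc) - x_px) / sx_px) -
    pnorm((seq_len(nc) - 1 - x_px) / sx_px)
  fy <- pnorm((seq_len(nr) - y_px) / sy_px) -
    pnorm((seq_len(nr) - 1 - y_px) / sy_px)
  offset + photons * outer(fy, fx)
}

# Independent spot localization via Nelder-Mead on the pixel-integrated
# Gaussian sum of squares (same model, independent optimizer / code path).
oracle_fit_spot_x <- function(window, x0, y0, s0) {
  rows <- seq_len(nrow(window)); cols <- seq_len(ncol(window))
  sse <- function(p) {
    fx <- pnorm((cols - p[1]) / exp(p[3])) - pnorm((cols - 1 - p[1]) / exp(p[3]))
    fy <- pnorm((rows - p[2]) / exp(p[4])) - pnorm((rows - 1 - p[2]) / exp(p[4]))
    sum((window - (p[6] + exp(p[5]) * outer(fy, fx)))^2)
  }
  amp0 <- max(sum(window - min(window)), 1)
  fit <- optim(c(x0, y0, log(s0), log(s0), log(amp0), min(window)), sse,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  fit$par[1]
}

make_small_truth <- function(radius = 100, offset = 50, voxel_edge = 10) {
  generate_ground_truth_synapse(synapse_geometry(
    center_a = c(0, 0, 0), radii_a = radius,
    center_b = c(offset, 0, 0), radii_b = radius,
    voxel_edge = voxel_edge))
}
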