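# Object-based two-channel cluster colocalization on a 10-nm voxel grid:
# voxelize localizations, smooth + Otsu-binarize, keep the largest connected
# component per channel, then compute directional Manders coefficients,
# volumes, volume ratios and the center-of-mass distance.

#' Bin localizations onto a 3D voxel grid
#'
#' Half-open binning: a coordinate exactly on an interior bin edge goes to the
#' higher bin. Each in-bounds record increments exactly one voxel.
#'
#' @param locs A localization table with finite `x_nm`, `y_nm`, `z_nm`.
#' @param voxel_edge Voxel edge, nm (default 10).
#' @param bounds List with `x`, `y`, `z`, each `c(lo, hi)` nm, covering the
#'   region of interest.
#' @param channel Optional channel label to select (and record).
#' @return An object of class `voxel_volume`: `counts` (3D array, x-by-y-by-z),
#'   `voxel_edge`, `origin`, `channel`, `n_localizations`.
#' @export
voxelize_localizations <- function(locs, voxel_edge = 10, bounds,
                                   channel = NULL) {
  stopifnot(is.data.frame(locs))
  check_scalar(voxel_edge, "voxel_edge", positive = TRUE)
  if (!is.null(channel)) locs <- locs[locs$channel == channel, , drop = FALSE]
  locs <- locs[is.finite(locs$x_nm) & is.finite(locs$y_nm) & is.finite(locs$z_nm), ,
               drop = FALSE]
  lo <- c(bounds$x[1], bounds$y[1], bounds$z[1])
  hi <- c(bounds$x[2], bounds$y[2], bounds$z[2])
  dims <- as.integer(ceiling((hi - lo) / voxel_edge))
  ix <- floor((locs$x_nm - lo[1]) / voxel_edge) + 1
  iy <- floor((locs$y_nm - lo[2]) / voxel_edge) + 1
  iz <- floor((locs$z_nm - lo[3]) / voxel_edge) + 1
  inb <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] & iz >= 1 & iz <= dims[3]
  if (!any(inb)) {
    abort("No localization falls inside the bounds; no cluster computable.")
  }
  lin <- (iz[inb] - 1) * dims[1] * dims[2] + (iy[inb] - 1) * dims[1] + ix[inb]
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  structure(
    list(counts = counts, voxel_edge = voxel_edge, origin = lo,
         channel = channel %||% NA_character_, n_localizations = sum(inb)),
    class = "voxel_volume"
  )
}

#' Construct a voxel volume from a 3D count array
#'
#' @param counts Numeric 3D array of non-negative counts (x-by-y-by-z).
#' @param voxel_edge Voxel edge, nm (default 10).
#' @param origin nm coordinates of the low corner of voxel `[1,1,1]`
#'   (default `c(0, 0, 0)`).
#' @param channel Optional channel label.
#' @return A `voxel_volume` object.
#' @export
voxel_volume <- function(counts, voxel_edge = 10, origin = c(0, 0, 0),
                         channel = NA_character_) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L, all(counts >= 0))
  check_scalar(voxel_edge, "voxel_edge", positive = TRUE)
  structure(
    list(counts = counts, voxel_edge = voxel_edge, origin = as.numeric(origin),
         channel = channel, n_localizations = sum(counts)),
    class = "voxel_volume"
  )
}

# Connected components of a logical 3D array under 6- or 26-connectivity,
# via an explicit voxel-adjacency edge list and igraph.
label_components_3d <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  d <- dim(mask)
  pos <- which(mask)
  if (length(pos) == 0) return(list(membership = integer(0), pos = pos))
  rank <- integer(prod(d))
  rank[pos] <- seq_along(pos)
  ix <- ((pos - 1L) %% d[1]) + 1L
  iy <- (((pos - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((pos - 1L) %/% (d[1] * d[2])) + 1L
  if (connectivity == 6) {
    offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26) {
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                                                 (offs[, 2] == 0 & offs[, 1] > 0)))
    offs <- offs[keep, , drop = FALSE] # forward half-neighborhood
  } else {
    abort("`connectivity` must be 6 or 26.")
  }
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nx <- ix + offs[k, 1]; ny <- iy + offs[k, 2]; nz <- iz + offs[k, 3]
    valid <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    nlin <- (nz[valid] - 1L) * d[1] * d[2] + (ny[valid] - 1L) * d[1] + nx[valid]
    hit <- rank[nlin] > 0L
    if (any(hit)) {
      edges[[k]] <- cbind(rank[pos[valid]][hit], rank[nlin][hit])
    }
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(pos), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) {
    g <- igraph::add_edges(g, t(el))
  }
  list(membership = igraph::components(g)$membership, pos = pos)
}

#' Segment the major cluster from a voxel volume
#'
#' The counts are smoothed with a 3D Gaussian filter (radius
#' `filter_radius` voxels, sigma = radius/2 by default), binarized with the
#' Otsu algorithm on a 256-bin histogram, split into connected components, and
#' the largest component is kept; all smaller components are discarded. Ties
#' in component size are broken toward the component containing the smallest
#' voxel index in scan order.
#'
#' @param volume A [voxelize_localizations()] result, or any `voxel_volume`.
#' @param filter_radius Gaussian filter radius, voxels (default 2, i.e. 20 nm
#'   at 10-nm voxels).
#' @param sigma Gaussian sigma in voxels (default `filter_radius / 2`; set
#'   `sigma = filter_radius` for the alternative convention).
#' @param connectivity 26 (default) or 6.
#' @return An object of class `cluster_mask`: `mask` (logical 3D array),
#'   `voxel_count`, `com` (nm), `voxel_edge`, `origin`, `connectivity`.
#' @export
segment_major_cluster <- function(volume, filter_radius = 2,
                                  sigma = filter_radius / 2,
                                  connectivity = 26) {
  stopifnot(inherits(volume, "voxel_volume"))
  x <- volume$counts
  if (max(x) == min(x)) {
    abort("Voxel volume is constant: Otsu binarization undefined.")
  }
  sm <- gaussian_smooth(x, sigma = sigma)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask)) abort("Binarization produced an empty mask.")
  lab <- label_components_3d(mask, connectivity = connectivity)
  sizes <- tabulate(lab$membership)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_pos <- vapply(best, function(b) min(lab$pos[lab$membership == b]),
                        numeric(1))
    best <- best[which.min(first_pos)]
  }
  keep <- lab$pos[lab$membership == best]
  major <- array(FALSE, dim = dim(mask))
  major[keep] <- TRUE
  idx <- which(major, arr.ind = TRUE)
  com <- volume$origin + (colMeans(idx) - 0.5) * volume$voxel_edge
  structure(
    list(mask = major, voxel_count = length(keep), com = unname(com),
         voxel_edge = volume$voxel_edge, origin = volume$origin,
         channel = volume$channel, connectivity = connectivity,
         threshold = thr, n_components = length(sizes)),
    class = "cluster_mask"
  )
}

#' Colocalization metrics between two cluster masks
#'
#' Directional Manders coefficients (fraction of the reference cluster's
#' voxels that are positive in the other channel), cluster volumes in voxels
#' and nm^3, the volume ratio, and the Euclidean center-of-mass distance.
#'
#' @param mask_a,mask_b [segment_major_cluster()] results on the same grid.
#' @return A one-row tibble with columns `manders_a_in_b`, `manders_b_in_a`,
#'   `voxels_a`, `voxels_b`, `volume_a_nm3`, `volume_b_nm3`,
#'   `volume_ratio_a_over_b`, `com_distance_nm`.
#' @export
colocalization_metrics <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "cluster_mask"), inherits(mask_b, "cluster_mask"))
  if (!identical(dim(mask_a$mask), dim(mask_b$mask)) ||
      !isTRUE(all.equal(mask_a$origin, mask_b$origin)) ||
      mask_a$voxel_edge != mask_b$voxel_edge) {
    abort("Cluster masks do not share the same grid geometry.")
  }
  na <- mask_a$voxel_count; nb <- mask_b$voxel_count
  nov <- sum(mask_a$mask & mask_b$mask)
  edge <- mask_a$voxel_edge
  tibble(
    manders_a_in_b = nov / na,
    manders_b_in_a = nov / nb,
    voxels_a = na, voxels_b = nb,
    volume_a_nm3 = na * edge^3, volume_b_nm3 = nb * edge^3,
    volume_ratio_a_over_b = na / nb,
    com_distance_nm = sqrt(sum((mask_a$com - mask_b$com)^2))
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels at %g nm, %d localizations, channel %s\n",
              paste(dim(x$counts), collapse = " x "), x$voxel_edge,
              x$n_localizations, x$channel))
  invisible(x)
}

#' @export
print.cluster_mask <- function(x, ...) {
  cat(sprintf("<cluster_mask> %d voxels (of %d components), COM (%.1f, %.1f, %.1f) nm\n",
              x$voxel_count, x$n_components, x$com[1], x$com[2], x$com[3]))
  invisible(x)
}
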