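# Ground-truth synapse geometry: two protein clusters (spheres or ellipsoids)
# rasterized exhaustively onto a 10-nm voxel grid, with exact voxel volumes,
# centers of mass and directional overlap fractions recorded as truth.

#' Specify a two-channel synapse cluster geometry
#'
#' Each channel's protein cluster is a sphere or axis-aligned ellipsoid given
#' by its center and radii in nm. The bounding box defaults to the union of
#' the two clusters padded by five voxels and snapped to the voxel grid.
#'
#' @param center_a,center_b Cluster centers, numeric length-3 (nm).
#' @param radii_a,radii_b Cluster radii, scalar (sphere) or length-3
#'   (ellipsoid), nm. Must be at least 3 voxel edges.
#' @param voxel_edge Voxel edge length in nm (default 10).
#' @param bounds Optional list with elements `x`, `y`, `z`, each `c(lo, hi)`
#'   in nm.
#' @return An object of class `synapse_geometry`.
#' @export
synapse_geometry <- function(center_a, radii_a, center_b, radii_b,
                             voxel_edge = 10, bounds = NULL) {
  check_scalar(voxel_edge, "voxel_edge", positive = TRUE)
  fix3 <- function(v, name) {
    if (length(v) == 1L) v <- rep(v, 3L)
    if (length(v) != 3L || !is.numeric(v)) {
      abort(sprintf("`%s` must be numeric of length 1 or 3.", name))
    }
    as.numeric(v)
  }
  center_a <- fix3(center_a, "center_a"); center_b <- fix3(center_b, "center_b")
  radii_a <- fix3(radii_a, "radii_a"); radii_b <- fix3(radii_b, "radii_b")
  if (any(c(radii_a, radii_b) < 3 * voxel_edge)) {
    abort("Cluster radii must be at least 3 voxel edges.")
  }
  if (is.null(bounds)) {
    pad <- 5 * voxel_edge
    lo <- pmin(center_a - radii_a, center_b - radii_b) - pad
    hi <- pmax(center_a + radii_a, center_b + radii_b) + pad
    lo <- floor(lo / voxel_edge) * voxel_edge
    hi <- ceiling(hi / voxel_edge) * voxel_edge
    bounds <- list(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]), z = c(lo[3], hi[3]))
  }
  for (ax in c("x", "y", "z")) {
    b <- bounds[[ax]]
    if (is.null(b) || length(b) != 2L || b[2] <= b[1]) {
      abort(sprintf("`bounds$%s` must be c(lo, hi) with hi > lo.", ax))
    }
  }
  structure(
    list(center_a = center_a, radii_a = radii_a,
         center_b = center_b, radii_b = radii_b,
         voxel_edge = voxel_edge, bounds = bounds),
    class = "synapse_geometry"
  )
}

# Voxel-center coordinates along one axis of a bounded grid.
voxel_centers <- function(lo, n, edge) lo + (seq_len(n) - 0.5) * edge

#' Rasterize a synapse geometry into ground-truth cluster masks
#'
#' Enumerates every voxel of the bounding box and marks it as belonging to a
#' cluster when its center lies inside the ellipsoid. The returned truth
#' record (volumes, centers of mass, directional overlap fractions, volume
#' ratio, center-of-mass distance) is computed by exhaustive voxel counting
#' and is therefore exact on the grid.
#'
#' @param geometry A [synapse_geometry()].
#' @return An object of class `ground_truth_synapse` with elements
#'   `mask_a`, `mask_b` (logical 3D arrays), `origin` (nm coordinates of the
#'   low corner of voxel `[1,1,1]`), `voxel_edge`, and `truth`, a one-row
#'   tibble of the exact derived quantities.
#' @export
generate_ground_truth_synapse <- function(geometry) {
  stopifnot(inherits(geometry, "synapse_geometry"))
  edge <- geometry$voxel_edge
  b <- geometry$bounds
  for (ch in c("a", "b")) {
    cc <- geometry[[paste0("center_", ch)]]
    rr <- geometry[[paste0("radii_", ch)]]
    lo <- c(b$x[1], b$y[1], b$z[1]); hi <- c(b$x[2], b$y[2], b$z[2])
    if (any(cc - rr < lo) || any(cc + rr > hi)) {
      abort(sprintf(
        "Cluster %s (center %s, radii %s) extends beyond the bounding box.",
        toupper(ch), paste(cc, collapse = ","), paste(rr, collapse = ",")))
    }
  }
  dims <- c(ceiling((b$x[2] - b$x[1]) / edge),
            ceiling((b$y[2] - b$y[1]) / edge),
            ceiling((b$z[2] - b$z[1]) / edge))
  origin <- c(b$x[1], b$y[1], b$z[1])
  cx <- voxel_centers(origin[1], dims[1], edge)
  cy <- voxel_centers(origin[2], dims[2], edge)
  cz <- voxel_centers(origin[3], dims[3], edge)
  inside <- function(center, radii) {
    dx2 <- ((cx - center[1]) / radii[1])^2
    dy2 <- ((cy - center[2]) / radii[2])^2
    dz2 <- ((cz - center[3]) / radii[3])^2
    outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  }
  mask_a <- inside(geometry$center_a, geometry$radii_a)
  mask_b <- inside(geometry$center_b, geometry$radii_b)
  truth <- mask_truth(mask_a, mask_b, origin, edge)
  structure(
    list(mask_a = mask_a, mask_b = mask_b, origin = origin,
         voxel_edge = edge, geometry = geometry, truth = truth),
    class = "ground_truth_synapse"
  )
}

# Exhaustive voxel-count truth for a pair of masks on a shared grid.
mask_truth <- function(mask_a, mask_b, origin, edge) {
  com <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    origin + (colMeans(idx) - 0.5) * edge
  }
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na == 0 || nb == 0) abort("Empty cluster mask: geometry degenerate.")
  nov <- sum(mask_a & mask_b)
  com_a <- com(mask_a); com_b <- com(mask_b)
  tibble(
    voxels_a = na, voxels_b = nb,
    volume_a_nm3 = na * edge^3, volume_b_nm3 = nb * edge^3,
    overlap_a_in_b = nov / na, overlap_b_in_a = nov / nb,
    volume_ratio_a_over_b = na / nb,
    com_ax = com_a[1], com_ay = com_a[2], com_az = com_a[3],
    com_bx = com_b[1], com_by = com_b[2], com_bz = com_b[3],
    com_distance_nm = sqrt(sum((com_a - com_b)^2))
  )
}

#' Find a two-sphere geometry with a target directional overlap fraction
#'
#' Keeps channel A fixed (sphere of radius `radius_a`) and the inter-center
#' offset fixed at `com_offset` along x, and searches the radius of sphere B
#' so that the voxel-exact overlap fraction of A inside B matches `overlap`.
#' The achieved (voxel-exact) truth is what downstream recovery is judged
#' against.
#'
#' @param overlap Target overlap fraction of cluster A inside cluster B.
#' @param com_offset Center-of-mass offset along x in nm (default 50).
#' @param radius_a Radius of sphere A in nm (default 150).
#' @param voxel_edge Voxel edge in nm (default 10).
#' @param tol Acceptable |achieved - target| (default 0.01).
#' @return A `ground_truth_synapse` whose `truth$overlap_a_in_b` is within
#'   `tol` of `overlap`.
#' @export
geometry_for_overlap <- function(overlap, com_offset = 50, radius_a = 150,
                                 voxel_edge = 10, tol = 0.01) {
  stopifnot(overlap > 0, overlap <= 1)
  make <- function(rb) {
    geom <- synapse_geometry(
      center_a = c(0, 0, 0), radii_a = radius_a,
      center_b = c(com_offset, 0, 0), radii_b = rb,
      voxel_edge = voxel_edge)
    generate_ground_truth_synapse(geom)
  }
  lo <- max(3 * voxel_edge, radius_a * 0.2)
  hi <- radius_a + com_offset + voxel_edge
  f <- function(rb) make(rb)$truth$overlap_a_in_b - overlap
  flo <- f(lo)
  if (flo >= 0) hi <- lo
  for (i in seq_len(40)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol / 2 || (hi - lo) < voxel_edge / 50) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  out <- make((lo + hi) / 2)
  if (abs(out$truth$overlap_a_in_b - overlap) > tol) {
    warn(sprintf("geometry_for_overlap: achieved %.3f for target %.3f",
                 out$truth$overlap_a_in_b, overlap))
  }
  out
}

#' @export
print.ground_truth_synapse <- function(x, ...) {
  cat("<ground_truth_synapse>\n")
  cat(sprintf("  grid: %s voxels at %g nm\n",
              paste(dim(x$mask_a), collapse = " x "), x$voxel_edge))
  t <- x$truth
  cat(sprintf("  volumes: A %d vox, B %d vox (ratio %.3f)\n",
              t$voxels_a, t$voxels_b, t$volume_ratio_a_over_b))
  cat(sprintf("  overlap: A-in-B %.3f, B-in-A %.3f; COM distance %.1f nm\n",
              t$overlap_a_in_b, t$overlap_b_in_a, t$com_distance_nm))
  invisible(x)
}
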