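#' Shape features (14) of a binary mask
#'
#' Mesh quantities (MeshVolume, SurfaceArea and derived ratios) come from a
#' marching-cubes surface of the mask: the 0/1 indicator is first smoothed
#' with a small Gaussian (sigma 0.8 voxel) and the 0.5 iso-level is meshed,
#' which removes the staircase bias of meshing the raw binary surface so that
#' area and volume converge to the continuum values on digitized spheres; for
#' masks too small to survive the smoothing, the raw indicator is meshed
#' instead, and for a single-voxel mask the mesh features are `NA`.
#' Axis lengths are `4 * sqrt(eigenvalue)` of the covariance of the physical
#' voxel-centre coordinates; Elongation and Flatness are square roots of
#' eigenvalue ratios. Maximum diameters are the largest pairwise distances
#' between boundary voxel centres, overall (3D) and within each orthogonal
#' plane family (fixed axis 3 = Slice, fixed axis 2 = Column, fixed axis 1 =
#' Row). Shape features depend only on the mask geometry, never on
#' intensities, bin width or pixel distance.
#'
#' @param mask An [rr_mask()].
#' @return Named numeric vector of 14 features.
#' @examples
#' m <- rr_mask(array(1, c(1, 1, 1)), spacing = c(1, 1, 1))
#' shape_features(m)[["VoxelVolume"]]
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "rr_mask"))
  vox <- mask$voxels
  sp <- mask$spacing
  n <- sum(vox)
  if (n < 1) stop("mask is empty")
  voxvol <- n * prod(sp)

  if (n == 1L) {
    av <- c(NA_real_, NA_real_)
  } else {
    ind <- array(as.double(vox), dim = dim(vox))
    sm <- gauss_smooth(ind, c(0.8, 0.8, 0.8))
    av <- mesh_area_volume(sm, sp)
    if (any(!is.finite(av)))
      av <- mesh_area_volume(ind, sp)
  }
  area <- av[1]
  mvol <- av[2]
  sphericity <- if (is.finite(area) && area > 0)
    pi^(1 / 3) * (6 * mvol)^(2 / 3) / area else NA_real_

  # principal axes from physical voxel-centre coordinates
  idx <- which(vox == 1L, arr.ind = TRUE)
  xyz <- sweep(idx - 1, 2, sp, "*")
  if (n > 1L) {
    ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_

  # boundary voxels: at least one 6-neighbour outside the mask (or off-grid)
  d <- dim(vox)
  padv <- array(0L, d + 2L)
  padv[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vox
  sl <- function(i, j, k) padv[i, j, k, drop = FALSE]
  core <- sl(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1))
  nb <- sl(1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)) +
        sl(3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)) +
        sl(2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)) +
        sl(2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)) +
        sl(2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]) +
        sl(2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2))
  bidx <- which(array(core == 1L & nb < 6L, d), arr.ind = TRUE)
  bxyz <- sweep(bidx - 1, 2, sp, "*")

  max3d <- max_pairwise_dist(bxyz)
  max2d <- function(fix_axis) {
    keep <- setdiff(1:3, fix_axis)
    groups <- split.data.frame(bxyz[, keep, drop = FALSE], bidx[, fix_axis])
    max(vapply(groups, function(g) max_pairwise_dist(as.matrix(g)), 0))
  }

  c(MeshVolume = mvol,
    VoxelVolume = voxvol,
    SurfaceArea = area,
    SurfaceVolumeRatio = if (is.finite(area)) area / mvol else NA_real_,
    Sphericity = sphericity,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d(3L),
    Maximum2DDiameterColumn = max2d(2L),
    Maximum2DDiameterRow = max2d(1L),
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = elong,
    Flatness = flat)
}

# largest pairwise Euclidean distance among rows of a coordinate matrix,
# chunked to bound memory
max_pairwise_dist <- function(xyz) {
  m <- nrow(xyz)
  if (m < 2L) return(0)
  sq <- rowSums(xyz^2)
  best <- 0
  chunk <- 512L
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    g <- xyz[s:e, , drop = FALSE]
    d2 <- outer(sq[s:e], sq, "+") - 2 * g %*% t(xyz)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
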