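#' 3D image volume
#'
#' Container for a 3D scalar image on a regular (possibly anisotropic) grid.
#' The voxel at array index `(i, j, k)` has its centre at world coordinate
#' `origin + (c(i, j, k) - 1) * spacing` (mm).
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing Numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin Numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @return An object of class `rr_volume` with fields `voxels`, `spacing`,
#'   `origin`.
#' @examples
#' v <- rr_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 2))
#' dim(v$voxels)
#' @export
rr_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("volume contains non-finite values")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "rr_volume")
}

#' Binary 3D mask
#'
#' A binary region of interest on the same grid as a paired [rr_volume()].
#'
#' @param voxels 3D array coercible to logical (0/1).
#' @param spacing,origin Grid geometry, as in [rr_volume()].
#' @param check_connected If `TRUE` (default), require a single 26-connected
#'   foreground component.
#' @return An object of class `rr_mask`; `voxels` is stored as an integer 0/1
#'   array.
#' @export
rr_mask <- function(voxels, spacing, origin = c(0, 0, 0), check_connected = TRUE) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  stor <- array(as.integer(voxels != 0), dim = dim(voxels))
  if (sum(stor) < 1L)
    stop("mask has no foreground voxels")
  if (isTRUE(check_connected)) {
    ncomp <- cpp_n_components26(stor, dim(stor))
    if (ncomp != 1L)
      stop(sprintf("mask foreground has %d 26-connected components (expected 1)", ncomp))
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  structure(list(voxels = stor, spacing = spacing, origin = origin),
            class = "rr_mask")
}

#' @export
print.rr_volume <- function(x, ...) {
  cat(sprintf("<rr_volume> %s voxels, spacing (%s) mm, range [%.4g, %.4g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.rr_mask <- function(x, ...) {
  cat(sprintf("<rr_mask> %s grid, %d foreground voxels, spacing (%s) mm\n",
              paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

# check that mask and volume share one grid
check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("volume and mask shapes differ")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9)
    stop("volume and mask spacings differ")
  if (max(abs(volume$origin - mask$origin)) > 1e-9)
    stop("volume and mask origins differ")
  invisible(TRUE)
}

# world coordinates of voxel centres along one axis
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# physical voxel volume in mm^3
voxel_volume_mm3 <- function(spacing) prod(spacing)
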