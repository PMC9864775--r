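#' One point of the preprocessing parameter grid
#'
#' Bundles the four preprocessing parameters whose influence on feature
#' robustness is assessed: the gray-level bin width of the intensity
#' histogram, the Chebyshev pixel distance of the texture neighbourhoods, the
#' intensity interpolator, and the isotropic resampling resolution. The study
#' grid is bin width {10, 20, 40}, distance {1, 2, 4} voxels, interpolator
#' {nearest, linear, spline}, resolution {1, 2, 2.5} mm; other values are
#' allowed.
#'
#' @param bin_width Gray-level bin width (> 0).
#' @param pixel_distance Chebyshev neighbourhood offset in voxels (>= 1).
#' @param interpolator One of `"nearest"`, `"linear"`, `"spline"` (cubic
#'   B-spline, order 3).
#' @param resolution_mm Isotropic resampling resolution in mm (> 0).
#' @return An object of class `rr_config` with a stable `id` string used in
#'   output file names.
#' @examples
#' extraction_config(bin_width = 10, pixel_distance = 2)
#' @export
extraction_config <- function(bin_width = 20, pixel_distance = 1,
                              interpolator = c("linear", "nearest", "spline"),
                              resolution_mm = 2) {
  interpolator <- match.arg(interpolator)
  if (bin_width <= 0) stop("'bin_width' must be > 0")
  if (pixel_distance < 1) stop("'pixel_distance' must be >= 1")
  if (resolution_mm <= 0) stop("'resolution_mm' must be > 0")
  id <- sprintf("bw%s_d%d_%s_r%s", format(bin_width), as.integer(pixel_distance),
                interpolator, format(resolution_mm))
  structure(list(bin_width = bin_width,
                 pixel_distance = as.integer(pixel_distance),
                 interpolator = interpolator, resolution_mm = resolution_mm,
                 id = id),
            class = "rr_config")
}

#' @export
print.rr_config <- function(x, ...) {
  cat(sprintf("<rr_config> %s\n", x$id))
  invisible(x)
}

#' The full factorial preprocessing grid
#'
#' @param bin_width,pixel_distance,interpolator,resolution_mm Vectors of
#'   values; defaults are the study grid (3 x 3 x 3 x 3 = 81 configurations).
#' @return A list of [extraction_config()] objects.
#' @export
config_grid <- function(bin_width = c(10, 20, 40),
                        pixel_distance = c(1, 2, 4),
                        interpolator = c("nearest", "linear", "spline"),
                        resolution_mm = c(1, 2, 2.5)) {
  g <- expand.grid(bin_width = bin_width, pixel_distance = pixel_distance,
                   interpolator = interpolator, resolution_mm = resolution_mm,
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    extraction_config(g$bin_width[i], g$pixel_distance[i],
                      g$interpolator[i], g$resolution_mm[i]))
}

# ---- resampling ------------------------------------------------------------

# cubic B-spline prefilter along the first dimension of a matrix (columns are
# independent signals); standard two-pass recursive filter, mirror boundary
bspline_prefilter_1d <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m)
  z <- sqrt(3) - 2
  m <- m * 6
  # causal initialisation under whole-sample mirror boundary: truncated
  # geometric sum when the horizon fits, exact periodic formula otherwise
  k0 <- ceiling(log(1e-12) / log(abs(z)))
  cp <- matrix(0, n, ncol(m))
  if (k0 < n) {
    init <- m[1, ]
    zk <- 1
    for (k in 2:k0) {
      zk <- zk * z
      init <- init + zk * m[k, ]
    }
  } else {
    # sum over one mirrored period x(0..n-1), x(n-2..1)
    init <- m[1, ]
    zk <- 1
    for (k in 2:n) {
      zk <- zk * z
      init <- init + zk * m[k, ]
    }
    if (n > 2) {
      for (k in (n - 1):2) {
        zk <- zk * z
        init <- init + zk * m[k, ]
      }
    }
    init <- init / (1 - zk * z)
  }
  cp[1, ] <- init
  for (i in 2:n) cp[i, ] <- m[i, ] + z * cp[i - 1, ]
  cm <- matrix(0, n, ncol(m))
  cm[n, ] <- (z / (z * z - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z * (cm[i + 1, ] - cp[i, ])
  cm
}

bspline_prefilter <- function(arr) {
  d <- dim(arr)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- bspline_prefilter_1d(matrix(a, nrow = d[ax]))
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  arr
}

# cubic B-spline kernel
bspline3 <- function(u) {
  au <- abs(u)
  ifelse(au < 1, (4 - 6 * au^2 + 3 * au^3) / 6,
         ifelse(au < 2, (2 - au)^3 / 6, 0))
}

# interpolate a 3D array at separable continuous indices tx, ty, tz (1-based)
interp3 <- function(arr, tx, ty, tz, method) {
  d <- dim(arr)
  if (method == "nearest") {
    ix <- pmin(pmax(floor(tx + 0.5), 1), d[1])
    iy <- pmin(pmax(floor(ty + 0.5), 1), d[2])
    iz <- pmin(pmax(floor(tz + 0.5), 1), d[3])
    return(arr[ix, iy, iz, drop = FALSE])
  }
  if (method == "linear") {
    out <- array(0, dim = c(length(tx), length(ty), length(tz)))
    i0x <- pmin(pmax(floor(tx), 1), d[1] - 1); fx <- tx - i0x
    i0y <- pmin(pmax(floor(ty), 1), d[2] - 1); fy <- ty - i0y
    i0z <- pmin(pmax(floor(tz), 1), d[3] - 1); fz <- tz - i0z
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      wx <- if (a == 0) 1 - fx else fx
      wy <- if (b == 0) 1 - fy else fy
      wz <- if (cc == 0) 1 - fz else fz
      w <- outer(outer(wx, wy), wz)
      out <- out + w * arr[i0x + a, i0y + b, i0z + cc, drop = FALSE]
    }
    return(out)
  }
  # cubic B-spline: prefilter to interpolating coefficients, 4 taps per axis
  cf <- bspline_prefilter(arr)
  out <- array(0, dim = c(length(tx), length(ty), length(tz)))
  i0x <- floor(tx); i0y <- floor(ty); i0z <- floor(tz)
  for (a in -1:2) for (b in -1:2) for (cc in -1:2) {
    wx <- bspline3(tx - (i0x + a))
    wy <- bspline3(ty - (i0y + b))
    wz <- bspline3(tz - (i0z + cc))
    w <- outer(outer(wx, wy), wz)
    ix <- reflect_whole(as.integer(i0x + a), d[1])
    iy <- reflect_whole(as.integer(i0y + b), d[2])
    iz <- reflect_whole(as.integer(i0z + cc), d[3])
    out <- out + w * cf[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Resample a volume and mask to isotropic resolution
#'
#' The volume is resampled with the requested interpolator (`"nearest"`,
#' trilinear `"linear"`, or order-3 cubic B-spline `"spline"`); the mask is
#' always resampled by nearest neighbour and stays binary. The output grid
#' keeps the input origin with spacing `(r, r, r)`; its extent matches the
#' input extent to within one voxel, and when the input is already isotropic
#' at `r` the grids coincide and values pass through unchanged.
#'
#' @param volume An [rr_volume()].
#' @param mask An [rr_mask()] aligned to `volume`.
#' @param resolution_mm Target isotropic spacing, mm (> 0).
#' @param interpolator Intensity interpolation scheme.
#' @return A list with elements `volume` and `mask` on the new grid.
#' @export
resample_volume <- function(volume, mask, resolution_mm,
                            interpolator = c("linear", "nearest", "spline")) {
  interpolator <- match.arg(interpolator)
  if (resolution_mm <= 0) stop("'resolution_mm' must be > 0")
  check_aligned(volume, mask)
  d <- dim(volume$voxels)
  sp <- volume$spacing
  nd <- pmax(1L, as.integer(floor((d - 1) * sp / resolution_mm + 1e-9)) + 1L)
  tx <- (seq_len(nd[1]) - 1) * resolution_mm / sp[1] + 1
  ty <- (seq_len(nd[2]) - 1) * resolution_mm / sp[2] + 1
  tz <- (seq_len(nd[3]) - 1) * resolution_mm / sp[3] + 1
  vox <- interp3(volume$voxels, tx, ty, tz, interpolator)
  mvox <- interp3(mask$voxels, tx, ty, tz, "nearest")
  if (sum(mvox) < 1)
    stop("resampled mask is empty (degenerate ROI at this resolution)")
  list(volume = rr_volume(vox, rep(resolution_mm, 3), volume$origin),
       mask = rr_mask(mvox, rep(resolution_mm, 3), volume$origin,
                      check_connected = FALSE))
}

# ---- discretization --------------------------------------------------------

#' Discretize in-mask intensities at fixed bin width
#'
#' Fixed-bin-size rule anchored at the in-mask minimum:
#' `level(x) = floor((x - min) / W) + 1`; the number of gray levels `Ng` is
#' the maximum level. Adding a constant to all in-mask intensities leaves the
#' levels unchanged.
#'
#' @param volume An [rr_volume()].
#' @param mask An [rr_mask()] aligned to `volume`.
#' @param bin_width Bin width `W` (> 0), in intensity units.
#' @return A list of class `rr_discretized`: `levels` (integer array, 0
#'   outside the mask), `ng`, `bin_width`, `n_voxels`.
#' @export
discretize <- function(volume, mask, bin_width) {
  if (bin_width <= 0) stop("'bin_width' must be > 0")
  check_aligned(volume, mask)
  sel <- mask$voxels == 1L
  if (!any(sel)) stop("mask is empty")
  vals <- volume$voxels[sel]
  lev <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  levels <- array(0L, dim = dim(volume$voxels))
  levels[sel] <- lev
  structure(list(levels = levels, ng = max(lev), bin_width = bin_width,
                 n_voxels = length(lev)),
            class = "rr_discretized")
}

# ---- wavelet ---------------------------------------------------------------

# coif1 analysis filters (frozen constants)
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

#' Single-level undecimated 3D coif1 wavelet decomposition
#'
#' Separable, undecimated (stationary) decomposition: the coiflet-1 low- and
#' high-pass analysis filters are applied along each axis in all eight
#' combinations, with symmetric (mirror) boundary padding. Sub-band labels
#' give the filter per axis in array order, e.g. `"HLL"` = high-pass along
#' axis 1, low-pass along axes 2 and 3. Each sub-band has the input's shape,
#' spacing and origin, so masks apply without re-registration. The transform
#' is linear and deterministic.
#'
#' @param volume An [rr_volume()]; each axis must be at least 6 voxels (the
#'   filter length).
#' @return Named list of eight [rr_volume()] sub-bands (`LLL`, `LLH`, `LHL`,
#'   `LHH`, `HLL`, `HLH`, `HHL`, `HHH`).
#' @export
wavelet_decompose <- function(volume) {
  stopifnot(inherits(volume, "rr_volume"))
  d <- dim(volume$voxels)
  if (any(d < length(COIF1_LO)))
    stop("every axis must be at least the filter length (6 voxels)")
  bands <- list(volume$voxels)
  labs <- ""
  for (ax in 1:3) {
    nxt <- vector("list", 2L * length(bands))
    nlabs <- character(2L * length(bands))
    for (i in seq_along(bands)) {
      nxt[[2L * i - 1L]] <- conv_axis(bands[[i]], COIF1_LO, ax)
      nlabs[2L * i - 1L] <- paste0(labs[i], "L")
      nxt[[2L * i]] <- conv_axis(bands[[i]], COIF1_HI, ax)
      nlabs[2L * i] <- paste0(labs[i], "H")
    }
    bands <- nxt
    labs <- nlabs
  }
  names(bands) <- labs
  order_lab <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- lapply(order_lab, function(nm)
    rr_volume(bands[[nm]], volume$spacing, volume$origin))
  names(out) <- order_lab
  out
}
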