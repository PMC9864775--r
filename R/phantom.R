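#' Specification of a synthetic CT-like lesion phantom
#'
#' Describes one phantom: an ellipsoidal lesion with spatially correlated
#' texture and additive noise on a CT-like anisotropic grid (in-plane spacing
#' finer than slice thickness), embedded in a homogeneous background.
#' Intensities are on an HU-like scale.
#'
#' @param grid_shape Integer length-3 voxel counts per axis (all >= 8).
#' @param spacing Voxel spacing in mm per axis.
#' @param lesion_center World coordinate (mm) of the lesion centre.
#' @param lesion_radii Ellipsoid semi-axes in mm (length 3).
#' @param lesion_mean_intensity Mean in-lesion intensity.
#' @param background_intensity Background intensity.
#' @param texture_amplitude Standard deviation of the spatially correlated
#'   in-lesion texture component.
#' @param texture_correlation_length Gaussian correlation length of the
#'   texture field, mm.
#' @param noise_sd Standard deviation of i.i.d. voxel noise (whole grid).
#' @param seed Integer RNG seed; the phantom is a pure function of the spec.
#' @param origin World coordinate (mm) of the first voxel centre.
#' @return An object of class `rr_phantom_spec`.
#' @examples
#' spec <- phantom_spec(seed = 1)
#' vol <- generate_phantom(spec)
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         spacing = c(0.7, 0.7, 1.25),
                         lesion_center = NULL,
                         lesion_radii = c(10, 10, 10),
                         lesion_mean_intensity = 20,
                         background_intensity = -800,
                         texture_amplitude = 40,
                         texture_correlation_length = 3,
                         noise_sd = 10,
                         seed = 1L,
                         origin = c(0, 0, 0)) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be 3 integers, all >= 8")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  if (is.null(lesion_center))
    lesion_center <- origin + (grid_shape - 1) * spacing / 2
  lesion_center <- as.numeric(lesion_center)
  lesion_radii <- as.numeric(lesion_radii)
  if (length(lesion_radii) != 3L || any(lesion_radii <= 0))
    stop("'lesion_radii' must be 3 positive values (mm)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (texture_amplitude < 0) stop("'texture_amplitude' must be >= 0")
  if (texture_correlation_length <= 0) stop("'texture_correlation_length' must be > 0")
  lo <- origin + 2 * spacing
  hi <- origin + (grid_shape - 3) * spacing
  if (any(lesion_center - lesion_radii < lo) || any(lesion_center + lesion_radii > hi))
    stop("lesion does not fit inside the grid with a 2-voxel margin")
  structure(list(grid_shape = grid_shape, spacing = spacing, origin = origin,
                 lesion_center = lesion_center, lesion_radii = lesion_radii,
                 lesion_mean_intensity = lesion_mean_intensity,
                 background_intensity = background_intensity,
                 texture_amplitude = texture_amplitude,
                 texture_correlation_length = texture_correlation_length,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "rr_phantom_spec")
}

#' The three segmentation styles
#'
#' `"accurate"`: the digitized ellipsoid, delineated as exactly as the grid
#' allows. `"rough_freehand"`: the lesion plus a margin of surrounding tissue
#' with a smooth random boundary. `"rough_polygon"`: a per-slice convex
#' polygon circumscribing the lesion cross-section with an outward margin.
#'
#' @return Character vector of the three style names.
#' @export
segmentation_styles <- function() c("accurate", "rough_freehand", "rough_polygon")

# squared normalized ellipsoid radius u^2 at every voxel centre
ellipsoid_u2 <- function(spec) {
  g <- spec$grid_shape
  cx <- axis_coords(g[1], spec$spacing[1], spec$origin[1])
  cy <- axis_coords(g[2], spec$spacing[2], spec$origin[2])
  cz <- axis_coords(g[3], spec$spacing[3], spec$origin[3])
  ux <- ((cx - spec$lesion_center[1]) / spec$lesion_radii[1])^2
  uy <- ((cy - spec$lesion_center[2]) / spec$lesion_radii[2])^2
  uz <- ((cz - spec$lesion_center[3]) / spec$lesion_radii[3])^2
  outer(outer(ux, uy, "+"), uz, "+")
}

#' Generate a phantom volume
#'
#' Background voxels take `background_intensity`; in-lesion voxels take
#' `lesion_mean_intensity` plus a Gaussian-smoothed, unit-variance texture
#' field scaled by `texture_amplitude`; i.i.d. Gaussian noise (`noise_sd`) is
#' added everywhere. Deterministic given `spec$seed`.
#'
#' @param spec An [phantom_spec()] object.
#' @return An [rr_volume()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "rr_phantom_spec"))
  set.seed(spec$seed)
  inside <- ellipsoid_u2(spec) <= 1
  vox <- array(spec$background_intensity, dim = spec$grid_shape)
  vox[inside] <- spec$lesion_mean_intensity
  if (spec$texture_amplitude > 0) {
    tex <- array(stats::rnorm(prod(spec$grid_shape)), dim = spec$grid_shape)
    tex <- gauss_smooth(tex, spec$texture_correlation_length / spec$spacing)
    tex <- (tex - mean(tex)) / stats::sd(tex)
    vox[inside] <- vox[inside] + spec$texture_amplitude * tex[inside]
  }
  if (spec$noise_sd > 0)
    vox <- vox + array(stats::rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
                       dim = spec$grid_shape)
  rr_volume(vox, spec$spacing, spec$origin)
}

#' Generate one segmentation of a phantom lesion
#'
#' Emulates three delineation styles: an accurate free-hand contour (the
#' digitized ellipsoid), a rough free-hand contour (accurate region dilated
#' by `margin_mm` with a smooth random radial perturbation of amplitude
#' `jitter_mm`), and a rough per-slice convex polygon circumscribing the
#' lesion cross-section inflated by `margin_mm`. The rough styles include the
#' lesion and some surrounding tissue; with `jitter_mm < margin_mm` they are
#' supersets of the accurate mask by construction.
#'
#' @param spec An [phantom_spec()] object.
#' @param style One of [segmentation_styles()].
#' @param seed Integer seed for the style's random perturbations.
#' @param margin_mm Outward margin of the rough styles, mm.
#' @param jitter_mm Amplitude (max absolute value) of the smooth boundary
#'   jitter of the rough free-hand style, mm.
#' @param poly_vertices Integer range of polygon vertex counts for the
#'   rough-polygon style.
#' @return An [rr_mask()].
#' @export
generate_segmentation <- function(spec, style, seed = spec$seed,
                                  margin_mm = 2, jitter_mm = 1,
                                  poly_vertices = c(6L, 10L)) {
  stopifnot(inherits(spec, "rr_phantom_spec"))
  style <- match.arg(tolower(style), segmentation_styles())
  u2 <- ellipsoid_u2(spec)
  accurate <- u2 <= 1
  if (style == "accurate")
    return(rr_mask(accurate, spec$spacing, spec$origin))

  # grid-fit check for the inflated region
  reach <- spec$lesion_radii + margin_mm + jitter_mm
  if (style == "rough_polygon") {
    kmin <- min(poly_vertices)
    reach[1:2] <- (spec$lesion_radii[1:2] + margin_mm) / cos(pi / kmin) + jitter_mm
  }
  lo <- spec$origin
  hi <- spec$origin + (spec$grid_shape - 1) * spec$spacing
  if (any(spec$lesion_center - reach < lo) || any(spec$lesion_center + reach > hi))
    stop("margin pushes the rough segmentation outside the grid")

  set.seed(as.integer(seed))
  g <- spec$grid_shape
  if (style == "rough_freehand") {
    cx <- axis_coords(g[1], spec$spacing[1], spec$origin[1]) - spec$lesion_center[1]
    cy <- axis_coords(g[2], spec$spacing[2], spec$origin[2]) - spec$lesion_center[2]
    cz <- axis_coords(g[3], spec$spacing[3], spec$origin[3]) - spec$lesion_center[3]
    d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
    dist <- sqrt(d2)
    # directional ellipsoid radius R(d): |x - c| / sqrt(u2), guarded at centre
    R <- ifelse(dist > 0, dist / sqrt(pmax(u2, 1e-12)), max(spec$lesion_radii))
    if (jitter_mm > 0) {
      jit <- array(stats::rnorm(prod(g)), dim = g)
      jit <- gauss_smooth(jit, 5 / spec$spacing) # ~5 mm correlation
      jit <- jit / max(abs(jit)) * jitter_mm
    } else {
      jit <- array(0, dim = g)
    }
    m <- (dist <= R + margin_mm + jit) | accurate
    return(rr_mask(m, spec$spacing, spec$origin))
  }

  # rough_polygon: per-slice circumscribing K-gon of the inflated ellipse
  k <- if (length(poly_vertices) > 1)
    sample(seq(min(poly_vertices), max(poly_vertices)), 1L) else as.integer(poly_vertices)
  m <- array(FALSE, dim = g)
  cx <- axis_coords(g[1], spec$spacing[1], spec$origin[1]) - spec$lesion_center[1]
  cy <- axis_coords(g[2], spec$spacing[2], spec$origin[2]) - spec$lesion_center[2]
  zc <- axis_coords(g[3], spec$spacing[3], spec$origin[3])
  X <- matrix(cx, nrow = g[1], ncol = g[2])
  Y <- matrix(cy, nrow = g[1], ncol = g[2], byrow = TRUE)
  for (iz in seq_len(g[3])) {
    t2 <- 1 - ((zc[iz] - spec$lesion_center[3]) / spec$lesion_radii[3])^2
    if (t2 <= 0) next
    a <- spec$lesion_radii[1] * sqrt(t2) + margin_mm
    b <- spec$lesion_radii[2] * sqrt(t2) + margin_mm
    phase <- stats::runif(1, 0, 2 * pi)
    ok <- matrix(TRUE, g[1], g[2])
    for (j in seq_len(k)) {
      th <- phase + 2 * pi * (j - 1) / k
      px <- a * cos(th); py <- b * sin(th)
      nx <- cos(th) / a; ny <- sin(th) / b
      ok <- ok & (nx * (X - px) + ny * (Y - py) <= 0)
    }
    m[, , iz] <- ok
  }
  m <- m | accurate
  rr_mask(m, spec$spacing, spec$origin)
}

#' Cohort parameter ranges for the synthetic generator
#'
#' Per-patient lesion parameters are drawn uniformly from these ranges.
#' Defaults emulate a pre-surgical lung-lesion cohort on a fixed scanner:
#' lesions 10--24 mm in diameter with mild anisotropy, soft-tissue mean
#' intensity on an aerated-lung background (about -800 HU-like units),
#' correlated texture and CT-like noise.
#'
#' @param base_radius Range (mm) of the largest lesion semi-axis.
#' @param axis_ratio Range of the per-axis shrink factor applied to
#'   `base_radius` (controls elongation/flatness).
#' @param lesion_mean Range of mean in-lesion intensity.
#' @param texture_amplitude Range of the texture-field SD.
#' @param noise_sd Range of the i.i.d. noise SD.
#' @param correlation_length Texture correlation length, mm (fixed).
#' @param background Background intensity (fixed).
#' @param grid_shape,spacing Grid geometry shared by all phantoms.
#' @param center_jitter Max absolute lesion-centre offset from the grid
#'   centre, mm per axis.
#' @param margin_mm,jitter_mm Rough-segmentation margin and jitter, mm.
#' @return A named list of ranges, class `rr_cohort_ranges`.
#' @export
cohort_ranges <- function(base_radius = c(5, 12),
                          axis_ratio = c(0.7, 1),
                          lesion_mean = c(-20, 40),
                          texture_amplitude = c(20, 60),
                          noise_sd = c(5, 20),
                          correlation_length = 3,
                          background = -800,
                          grid_shape = c(64, 64, 48),
                          spacing = c(0.7, 0.7, 1.25),
                          center_jitter = 2,
                          margin_mm = 2,
                          jitter_mm = 1) {
  structure(list(base_radius = base_radius, axis_ratio = axis_ratio,
                 lesion_mean = lesion_mean,
                 texture_amplitude = texture_amplitude, noise_sd = noise_sd,
                 correlation_length = correlation_length,
                 background = background, grid_shape = grid_shape,
                 spacing = spacing, center_jitter = center_jitter,
                 margin_mm = margin_mm, jitter_mm = jitter_mm),
            class = "rr_cohort_ranges")
}

#' Generate a synthetic phantom cohort
#'
#' Draws per-patient lesion parameters from `ranges`, builds each phantom and
#' its three segmentations. A pure function of `(n_patients, master_seed,
#' ranges)`: per-patient sub-seeds are derived from `master_seed`, and each
#' segmentation style uses its own derived seed.
#'
#' @param n_patients Number of patients (>= 2); the emulated study size is 48.
#' @param master_seed Integer master seed.
#' @param ranges A [cohort_ranges()] object.
#' @return A list of class `rr_cohort`; each element has fields `id`,
#'   `volume`, `masks` (named list over [segmentation_styles()]), `spec`.
#' @examples
#' coh <- generate_cohort(2, master_seed = 7)
#' names(coh[[1]]$masks)
#' @export
generate_cohort <- function(n_patients = 48L, master_seed = 1L,
                            ranges = cohort_ranges()) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("'n_patients' must be >= 2")
  stopifnot(inherits(ranges, "rr_cohort_ranges"))
  set.seed(as.integer(master_seed))
  runif2 <- function(r, n) stats::runif(n, r[1], r[2])
  base_r <- runif2(ranges$base_radius, n_patients)
  ratios <- matrix(runif2(ranges$axis_ratio, 3 * n_patients), ncol = 3)
  lmean <- runif2(ranges$lesion_mean, n_patients)
  tamp <- runif2(ranges$texture_amplitude, n_patients)
  nsd <- runif2(ranges$noise_sd, n_patients)
  cjit <- matrix(stats::runif(3 * n_patients, -ranges$center_jitter,
                              ranges$center_jitter), ncol = 3)
  sub_seed <- sample.int(1e8L, n_patients)
  centre0 <- (ranges$grid_shape - 1) * ranges$spacing / 2
  out <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    # the largest axis keeps base_r; the others shrink by the drawn ratios
    radii <- base_r[i] * ratios[i, ] / max(ratios[i, ])
    spec <- phantom_spec(grid_shape = ranges$grid_shape,
                         spacing = ranges$spacing,
                         lesion_center = centre0 + cjit[i, ],
                         lesion_radii = radii,
                         lesion_mean_intensity = lmean[i],
                         background_intensity = ranges$background,
                         texture_amplitude = tamp[i],
                         texture_correlation_length = ranges$correlation_length,
                         noise_sd = nsd[i],
                         seed = sub_seed[i])
    vol <- generate_phantom(spec)
    styles <- segmentation_styles()
    masks <- lapply(seq_along(styles), function(k)
      generate_segmentation(spec, styles[k], seed = sub_seed[i] + k * 100000000L,
                            margin_mm = ranges$margin_mm,
                            jitter_mm = ranges$jitter_mm))
    names(masks) <- styles
    out[[i]] <- list(id = sprintf("P%03d", i), volume = vol, masks = masks,
                     spec = spec)
  }
  class(out) <- "rr_cohort"
  out
}

#' @export
print.rr_cohort <- function(x, ...) {
  cat(sprintf("<rr_cohort> %d patients, %d masks (%s)\n", length(x),
              3L * length(x), paste(segmentation_styles(), collapse = ", ")))
  invisible(x)
}
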