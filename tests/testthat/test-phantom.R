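# Synthetic phantom-cohort generator

small_spec <- function(lesion_radii = c(6, 5, 6), seed = 11L, ...) {
  phantom_spec(grid_shape = c(32, 32, 24), spacing = c(0.7, 0.7, 1.25),
               lesion_radii = lesion_radii, seed = seed, ...)
}

test_that("noise-free phantom is piecewise constant at the stated intensities", {
  spec <- small_spec(texture_amplitude = 0, noise_sd = 0,
                     lesion_mean_intensity = 25, background_intensity = -800)
  vol <- generate_phantom(spec)
  msk <- generate_segmentation(spec, "accurate")
  inside <- msk$voxels == 1L
  expect_true(all(vol$voxels[inside] == 25))
  expect_true(all(vol$voxels[!inside] == -800))
})

test_that("phantom generation is deterministic given the seed", {
  spec <- small_spec()
  expect_identical(generate_phantom(spec)$voxels, generate_phantom(spec)$voxels)
})

test_that("in-lesion noise SD matches the generator's noise model", {
  spec <- small_spec(texture_amplitude = 0, noise_sd = 10, seed = 5L)
  vol <- generate_phantom(spec)
  msk <- generate_segmentation(spec, "accurate")
  vals <- vol$voxels[msk$voxels == 1L]
  expect_gt(length(vals), 1000)
  expect_lt(abs(sd(vals) - 10) / 10, 0.15)
})

test_that("lesion that does not fit in the grid is rejected", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 16), spacing = c(1, 1, 1),
                            lesion_radii = c(20, 5, 5)),
               "fit")
  expect_error(phantom_spec(grid_shape = c(6, 64, 48)), "grid_shape")
  expect_error(small_spec(noise_sd = -1), "noise_sd")
})

test_that("accurate segmentation equals the digitized ellipsoid", {
  spec <- small_spec()
  msk <- generate_segmentation(spec, "accurate")
  # independent digitization
  g <- spec$grid_shape
  expect_mask <- array(FALSE, g)
  for (ix in 1:g[1]) for (iy in 1:g[2]) for (iz in 1:g[3]) {
    p <- spec$origin + (c(ix, iy, iz) - 1) * spec$spacing
    u2 <- sum(((p - spec$lesion_center) / spec$lesion_radii)^2)
    expect_mask[ix, iy, iz] <- u2 <= 1
  }
  expect_identical(msk$voxels == 1L, expect_mask)
})

test_that("rough free-hand mask with zero jitter strictly contains the accurate mask", {
  spec <- small_spec()
  acc <- generate_segmentation(spec, "accurate")
  rough <- generate_segmentation(spec, "rough_freehand", seed = 3, jitter_mm = 0)
  expect_true(all(rough$voxels[acc$voxels == 1L] == 1L))
  expect_gt(sum(rough$voxels), sum(acc$voxels))
})

test_that("rough polygon slices are convex supersets of the accurate slices", {
  spec <- small_spec()
  acc <- generate_segmentation(spec, "accurate")
  poly <- generate_segmentation(spec, "rough_polygon", seed = 9)
  expect_true(all(poly$voxels[acc$voxels == 1L] == 1L))
  for (iz in seq_len(dim(poly$voxels)[3])) {
    sl <- poly$voxels[, , iz]
    if (sum(sl) < 4) next
    pts <- which(sl == 1L, arr.ind = TRUE)
    hull <- grDevices::chull(pts)
    hp <- pts[hull, , drop = FALSE]
    # every lattice point inside the hull of the foreground must be foreground
    inside <- matrix(FALSE, nrow(sl), ncol(sl))
    for (ix in seq_len(nrow(sl))) for (iy in seq_len(ncol(sl))) {
      # point-in-polygon via winding over hull edges (all cross products same sign)
      v <- cbind(hp[, 1] - ix, hp[, 2] - iy)
      v2 <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
      cr <- v[, 1] * v2[, 2] - v[, 2] * v2[, 1]
      inside[ix, iy] <- all(cr <= 1e-9) || all(cr >= -1e-9)
    }
    expect_true(all(sl[inside] == 1L), label = sprintf("slice %d convexity", iz))
  }
})

test_that("all three masks contain the lesion centroid and are connected supersets", {
  spec <- small_spec()
  acc <- generate_segmentation(spec, "accurate")
  ctr <- round((spec$lesion_center - spec$origin) / spec$spacing) + 1
  for (style in segmentation_styles()) {
    m <- generate_segmentation(spec, style, seed = 21)
    expect_equal(m$voxels[ctr[1], ctr[2], ctr[3]], 1L)
    expect_gte(sum(m$voxels), sum(acc$voxels))
  }
})

test_that("margin pushing the rough mask outside the grid is rejected", {
  spec <- phantom_spec(grid_shape = c(32, 32, 24), spacing = c(1, 1, 1),
                      lesion_radii = c(12, 12, 8), seed = 2)
  expect_error(generate_segmentation(spec, "rough_freehand", margin_mm = 6),
               "outside the grid")
})

test_that("cohort generation is reproducible and spans the radius range", {
  c1 <- generate_cohort(2, master_seed = 99)
  c2 <- generate_cohort(2, master_seed = 99)
  expect_identical(c1[[1]]$volume$voxels, c2[[1]]$volume$voxels)
  expect_identical(c1[[2]]$masks$rough_polygon$voxels,
                   c2[[2]]$masks$rough_polygon$voxels)
  expect_error(generate_cohort(1), ">= 2")

  coh <- generate_cohort(10, master_seed = 4)
  expect_length(coh, 10)
  vols <- vapply(coh, function(p) sum(p$masks$accurate$voxels), 0)
  expect_gt(max(vols), min(vols))
  # superset ordering holds at default jitter < margin
  for (p in coh) {
    na <- sum(p$masks$accurate$voxels)
    expect_lte(na, sum(p$masks$rough_freehand$voxels))
    expect_lte(na, sum(p$masks$rough_polygon$voxels))
  }
})
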