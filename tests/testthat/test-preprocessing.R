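# Resampling, discretization, wavelet decomposition

iso_fixture <- function(seed = 1, d = c(10, 10, 10)) {
  set.seed(seed)
  vol <- rr_volume(array(rnorm(prod(d)), d), spacing = c(1, 1, 1))
  m <- array(0L, d)
  m[3:8, 3:8, 3:8] <- 1L
  list(vol = vol, mask = rr_mask(m, c(1, 1, 1)))
}

test_that("resampling an already-isotropic volume at its own resolution is the identity", {
  fx <- iso_fixture()
  for (itp in c("nearest", "linear", "spline")) {
    rs <- resample_volume(fx$vol, fx$mask, 1, itp)
    expect_equal(rs$volume$voxels, fx$vol$voxels, tolerance = 1e-8)
    expect_identical(rs$mask$voxels, fx$mask$voxels)
  }
})

test_that("masks stay binary and nearest-neighbour intensities stay in the input value set", {
  fx <- iso_fixture(2)
  vals <- c(-3, 0, 7)
  vol <- rr_volume(array(sample(vals, 1000, TRUE), c(10, 10, 10)), c(1, 1, 1))
  for (itp in c("nearest", "linear", "spline")) {
    rs <- resample_volume(vol, fx$mask, 0.8, itp)
    expect_true(all(rs$mask$voxels %in% c(0L, 1L)))
  }
  rs <- resample_volume(vol, fx$mask, 0.7, "nearest")
  expect_true(all(rs$volume$voxels %in% vals))
})

test_that("linear interpolation at a grid midpoint is the neighbour average", {
  d <- c(9, 4, 4)
  profile <- c(0, 10, 30, 70, 150, 160, 100, 40, 0)
  vol <- rr_volume(array(rep(profile, 16), d), c(1, 1, 1))
  m <- array(1L, d)
  mask <- rr_mask(m, c(1, 1, 1))
  rs <- resample_volume(vol, mask, 0.5, "linear")
  # output index 2 sits exactly between input voxels 1 and 2 along axis 1
  expect_equal(rs$volume$voxels[2, 1, 1], (profile[1] + profile[2]) / 2)
  expect_equal(rs$volume$voxels[4, 1, 1], (profile[2] + profile[3]) / 2)
})

test_that("degenerate resampling inputs are rejected", {
  fx <- iso_fixture()
  expect_error(resample_volume(fx$vol, fx$mask, 0), "> 0")
  tiny <- array(0L, c(10, 10, 10))
  tiny[3, 3, 3] <- 1L   # never the nearest voxel to any 8 mm sample point
  tiny <- rr_mask(tiny, c(1, 1, 1))
  expect_error(resample_volume(fx$vol, tiny, 8), "empty")
})

test_that("discretization follows the min-anchored fixed-bin-width rule", {
  mk <- function(vals) {
    d <- c(length(vals), 1, 1)
    list(vol = rr_volume(array(vals, d), c(1, 1, 1)),
         mask = rr_mask(array(1L, d), c(1, 1, 1)))
  }
  fx <- mk(c(0, 9.9, 10, 25))
  disc <- discretize(fx$vol, fx$mask, 10)
  expect_equal(as.vector(disc$levels), c(1, 1, 2, 3))
  expect_equal(disc$ng, 3)

  fx <- mk(rep(42, 5))
  disc <- discretize(fx$vol, fx$mask, 7)
  expect_true(all(disc$levels == 1L))
  expect_equal(disc$ng, 1)

  fx <- mk(c(-15, -5, 0, 20))
  disc <- discretize(fx$vol, fx$mask, 10)
  expect_equal(as.vector(disc$levels), c(1, 2, 2, 4))
  expect_equal(disc$ng, 4)
  # brute-force binning oracle: count bin edges below each value
  vals <- c(-15, -5, 0, 20)
  oracle <- vapply(vals, function(x) {
    l <- 1L
    while (x >= min(vals) + l * 10) l <- l + 1L
    l
  }, 1L)
  expect_equal(as.vector(disc$levels), as.vector(oracle))

  expect_error(discretize(fx$vol, fx$mask, 0), "> 0")
})

test_that("discretization is invariant to an additive intensity shift", {
  set.seed(3)
  d <- c(6, 6, 6)
  vals <- array(rnorm(prod(d), sd = 30), d)
  m <- rr_mask(array(1L, d), c(1, 1, 1))
  d1 <- discretize(rr_volume(vals, c(1, 1, 1)), m, 8)
  d2 <- discretize(rr_volume(vals + 123.456, c(1, 1, 1)), m, 8)
  expect_identical(d1$levels, d2$levels)
})

test_that("wavelet decomposition returns 8 same-shape sub-bands; high-pass of a constant vanishes", {
  vol <- rr_volume(array(5, c(8, 8, 8)), c(1, 1, 1))
  bands <- wavelet_decompose(vol)
  expect_named(bands, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  for (b in names(bands)) {
    expect_identical(dim(bands[[b]]$voxels), c(8L, 8L, 8L))
    if (grepl("H", b)) {
      expect_lt(max(abs(bands[[b]]$voxels)), 1e-8)
    } else {
      expect_lt(max(bands[[b]]$voxels) - min(bands[[b]]$voxels), 1e-8)
    }
  }
  expect_error(wavelet_decompose(rr_volume(array(0, c(4, 8, 8)), c(1, 1, 1))),
               "filter length")
})

test_that("impulse response of LLL matches a direct separable convolution oracle", {
  d <- c(9, 9, 9)
  arr <- array(0, d)
  arr[5, 5, 5] <- 1
  vol <- rr_volume(arr, c(1, 1, 1))
  lll <- wavelet_decompose(vol)$LLL$voxels
  # direct correlation oracle with the same centring and mirror padding
  lo <- radiorobust:::COIF1_LO
  centre <- (length(lo) - 1) %/% 2 + 1
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    j <- ifelse(j < 0, j + 2 * n, j)
    ifelse(j >= n, 2 * n - 1 - j, j) + 1
  }
  conv1 <- function(x, taps) {
    n <- length(x)
    vapply(seq_len(n), function(p)
      sum(taps * x[refl(p + seq_along(taps) - centre, n)]), 0)
  }
  oracle <- array(0, d)
  for (iy in 1:d[2]) for (iz in 1:d[3]) oracle[, iy, iz] <- conv1(arr[, iy, iz], lo)
  tmp <- oracle
  for (ix in 1:d[1]) for (iz in 1:d[3]) tmp[ix, , iz] <- conv1(oracle[ix, , iz], lo)
  oracle <- tmp
  for (ix in 1:d[1]) for (iy in 1:d[2]) tmp[ix, iy, ] <- conv1(oracle[ix, iy, ], lo)
  oracle <- tmp
  expect_equal(lll, oracle, tolerance = 1e-12)
  # away from boundaries the response is the separable product of low-pass taps
  taps_at <- function(i) { k <- centre - (i - 5); ifelse(k >= 1 & k <= 6, lo[k], 0) }
  expect_equal(lll[4, 6, 5], taps_at(4) * taps_at(6) * taps_at(5),
               tolerance = 1e-12)
})

test_that("wavelet decomposition is linear", {
  set.seed(8)
  d <- c(8, 8, 8)
  v1 <- array(rnorm(prod(d)), d)
  v2 <- array(rnorm(prod(d)), d)
  b1 <- wavelet_decompose(rr_volume(v1, c(1, 1, 1)))
  b2 <- wavelet_decompose(rr_volume(v2, c(1, 1, 1)))
  bc <- wavelet_decompose(rr_volume(2 * v1 - 3 * v2, c(1, 1, 1)))
  for (nm in names(bc))
    expect_lt(max(abs(bc[[nm]]$voxels -
                      (2 * b1[[nm]]$voxels - 3 * b2[[nm]]$voxels))), 1e-8)
})
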