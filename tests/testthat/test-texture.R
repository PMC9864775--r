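# Texture-matrix families vs hand fixtures and brute-force oracles

as_disc <- function(lv) {
  structure(list(levels = array(as.integer(lv), dim(lv)), ng = max(lv),
                 bin_width = 1, n_voxels = sum(lv > 0)),
            class = "rr_discretized")
}

test_that("constant region collapses every family to its degenerate values", {
  lv <- array(1L, c(3, 3, 3))
  disc <- as_disc(lv)
  g <- glcm_features(disc, 1)
  expect_equal(g[["Contrast"]], 0)
  expect_equal(g[["MaximumProbability"]], 1)
  expect_equal(g[["JointEntropy"]], 0)
  expect_equal(g[["JointEnergy"]], 1)
  expect_equal(g[["Correlation"]], 1)   # documented degenerate convention
  z <- glszm_features(disc)
  expect_equal(z[["ZonePercentage"]], 1 / 27)
  n <- ngtdm_features(disc, 1)
  expect_equal(n[["Contrast"]], 0)
  expect_equal(n[["Coarseness"]], 1e6)
  d <- gldm_features(disc, 1)
  # centre voxel of a constant 3x3x3 cube depends on all 26 neighbours
  D <- radiorobust:::cpp_gldm(disc$levels, dim(disc$levels), 1L, 1L, 0L)
  expect_equal(D[1, 27], 1L)  # dependence 26 -> column 27
  expect_equal(sum(D), 27L)
})

test_that("2x2x1 two-level fixture matches the exhaustive pair enumeration", {
  lv <- array(0L, c(2, 2, 1))
  lv[1, , 1] <- 1L
  lv[2, , 1] <- 2L
  disc <- as_disc(lv)
  counts <- radiorobust:::cpp_glcm(disc$levels, dim(disc$levels), 2L, 1L)
  # direction (1,0,0) is the first of the 13 directions
  Cx <- counts[, , 1]
  expect_equal(Cx, matrix(c(0, 2, 2, 0), 2, 2))
  fx <- radiorobust:::glcm_features_one(Cx, 2)
  expect_equal(fx[["Contrast"]], 1)
  expect_equal(fx[["MaximumProbability"]], 0.5)
  # whole-matrix agreement with the brute-force oracle: same multiset of
  # per-direction matrices (the direction enumeration order is arbitrary)
  key <- function(a) sort(apply(a, 3, paste, collapse = ","))
  expect_equal(key(counts), key(o_glcm_matrix(lv, 1)))
})

test_that("run-length fixtures match closed forms and the run-enumeration oracle", {
  # constant row of 5: one run of length 5 along the row direction
  lv <- array(1L, c(5, 1, 1))
  counts <- radiorobust:::cpp_glrlm(lv, dim(lv), 1L)
  expect_equal(counts[1, 5, 1], 1L)      # direction (1,0,0)
  expect_equal(sum(counts[, , 1]), 1L)
  lre_x <- radiorobust:::size_matrix_features(matrix(counts[1, , 1], 1), 5, "Run")
  expect_equal(lre_x[["LongRunEmphasis"]], 25)

  # alternating levels: all runs length 1 along the row
  lv <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  counts <- radiorobust:::cpp_glrlm(lv, dim(lv), 2L)
  expect_true(all(counts[, 2:4, 1] == 0L))
  rp <- radiorobust:::size_matrix_features(counts[, , 1], 4, "Run")
  expect_equal(rp[["RunPercentage"]], 1)
  key <- function(a) sort(apply(a, 3, paste, collapse = ","))
  expect_equal(key(counts), key(o_glrlm_matrix(lv)))
})

test_that("size zones equal 26-connected components of equal level", {
  lv <- array(1L, c(6, 4, 1))       # background level 1
  lv[1:2, 1, 1] <- 2L               # blob A: 3 voxels (L-shape)
  lv[1, 2, 1] <- 2L
  lv[5:6, 3:4, 1] <- 2L             # blob B: 4 voxels, grow to 5
  lv[4, 4, 1] <- 2L
  disc <- as_disc(lv)
  zones <- radiorobust:::cpp_glszm(disc$levels, dim(disc$levels))
  got <- zones[order(zones[, 1], zones[, 2]), , drop = FALSE]
  oz <- o_glszm_zones(lv)
  oz <- as.matrix(oz[order(oz$level, oz$size), ])
  expect_equal(unname(got), unname(oz))
  sizes2 <- sort(zones[zones[, 1] == 2, 2])
  expect_equal(sizes2, c(3L, 5L))
  # single-zone closed form
  const <- as_disc(array(1L, c(4, 4, 2)))
  expect_equal(glszm_features(const)[["ZonePercentage"]], 1 / 32)
})

test_that("NGTDM 1x3x1 fixture matches hand-computed sums and features", {
  lv <- array(c(1L, 2L, 1L), c(3, 1, 1))
  sn <- radiorobust:::cpp_ngtdm(lv, dim(lv), 2L, 1L)
  expect_equal(sn[, 1], c(2, 1))   # s_1 = 2, s_2 = 1
  expect_equal(sn[, 2], c(2, 1))   # n_1 = 2, n_2 = 1
  f <- ngtdm_features(as_disc(lv), 1)
  expect_equal(f[["Coarseness"]], 0.6)
  expect_equal(f[["Contrast"]], 2 / 9)
  expect_equal(f[["Busyness"]], 0)          # |1*p1 - 2*p2| = 0 here
  expect_equal(f[["Complexity"]], 10 / 9)
  expect_equal(f[["Strength"]], 2 / 3)
})

test_that("GLDM checkerboard dependencies come only from diagonal equal-level neighbours", {
  lv <- array(0L, c(4, 4, 2))
  for (x in 1:4) for (y in 1:4) for (z in 1:2)
    lv[x, y, z] <- 1L + (x + y + z) %% 2L
  D <- radiorobust:::cpp_gldm(lv, dim(lv), 2L, 1L, 0L)
  expect_equal(unname(D), unname(o_gldm_matrix(lv, 1)))
  # face neighbours always differ on a checkerboard: corner voxel of the
  # 4x4x2 block has 3 same-parity diagonal neighbours in-slab + 1 across
  f <- gldm_features(as_disc(lv), 1)
  fo <- o_gldm_features(o_gldm_matrix(lv, 1))
  expect_equal(unname(f), unname(fo), tolerance = 1e-12)
})

test_that("random small fixtures agree with all five brute-force oracles", {
  for (seed in 1:8) {
    disc <- rand_disc(seed, ng = 4L)
    lv <- disc$levels
    for (dist in c(1L, 2L)) {
      expect_equal(unname(glcm_features(disc, dist)),
                   unname(o_family_features(lv, "glcm", dist)),
                   tolerance = 1e-9, label = sprintf("glcm seed %d d %d", seed, dist))
      expect_equal(unname(ngtdm_features(disc, dist)),
                   unname(o_family_features(lv, "ngtdm", dist)),
                   tolerance = 1e-9, label = sprintf("ngtdm seed %d", seed))
      expect_equal(unname(gldm_features(disc, dist)),
                   unname(o_family_features(lv, "gldm", dist)),
                   tolerance = 1e-9, label = sprintf("gldm seed %d", seed))
    }
    expect_equal(unname(glrlm_features(disc)),
                 unname(o_family_features(lv, "glrlm")),
                 tolerance = 1e-9, label = sprintf("glrlm seed %d", seed))
    expect_equal(unname(glszm_features(disc)),
                 unname(o_family_features(lv, "glszm")),
                 tolerance = 1e-9, label = sprintf("glszm seed %d", seed))
  }
})

test_that("direction-averaged texture features are invariant to axis permutation", {
  disc <- rand_disc(42, ng = 3L)
  lv <- disc$levels
  perm <- aperm(lv, c(2, 3, 1))
  discp <- structure(list(levels = perm, ng = disc$ng, bin_width = 1,
                          n_voxels = disc$n_voxels), class = "rr_discretized")
  expect_equal(glcm_features(disc, 1), glcm_features(discp, 1), tolerance = 1e-9)
  expect_equal(glrlm_features(disc), glrlm_features(discp), tolerance = 1e-9)
  expect_equal(glszm_features(disc), glszm_features(discp), tolerance = 1e-9)
  expect_equal(ngtdm_features(disc, 1), ngtdm_features(discp, 1), tolerance = 1e-9)
  expect_equal(gldm_features(disc, 1), gldm_features(discp, 1), tolerance = 1e-9)
})

test_that("texture features are invariant to an intensity shift before discretization", {
  set.seed(9)
  d <- c(6, 5, 4)
  vals <- array(rnorm(prod(d), 0, 20), d)
  m <- rr_mask(array(1L, d), c(1, 1, 1))
  d1 <- discretize(rr_volume(vals, c(1, 1, 1)), m, 5)
  d2 <- discretize(rr_volume(vals + 77.7, c(1, 1, 1)), m, 5)
  expect_equal(glcm_features(d1, 1), glcm_features(d2, 1))
  expect_equal(glszm_features(d1), glszm_features(d2))
})
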