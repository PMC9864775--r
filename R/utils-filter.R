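# Separable filtering utilities shared by the phantom generator (texture
# smoothing), mesh anti-aliasing, and the wavelet transform.

# symmetric (half-sample, edge-repeating) reflection of out-of-range indices
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# whole-sample mirror (edge not repeated: index 0 -> 2), the boundary model
# of the recursive B-spline prefilter
reflect_whole <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  ifelse(j >= n, p - j, j) + 1L
}

# 1D correlation along one axis of a 3D array with symmetric padding.
# Tap k (1-based) multiplies x[n + k - centre]; centre = floor((L-1)/2) + 1.
conv_axis <- function(arr, taps, axis) {
  d <- dim(arr)
  n <- d[axis]
  L <- length(taps)
  centre <- ((L - 1L) %/% 2L) + 1L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  idx <- reflect_index((1L - (centre - 1L)):(n + (L - centre)), n)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (k in seq_len(L)) {
    if (taps[k] != 0)
      out <- out + taps[k] * mp[k:(k + n - 1L), , drop = FALSE]
  }
  b <- array(out, dim = d[perm])
  aperm(b, order(perm))
}

# isotropic-in-voxel-units Gaussian smoothing, sigma per axis (voxels)
gauss_smooth <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    arr <- conv_axis(arr, k, ax)
  }
  arr
}
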