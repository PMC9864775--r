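#' First-order intensity features (18)
#'
#' Moments and percentiles are computed from the raw in-mask intensities;
#' Entropy and Uniformity use the fixed-bin-width discretized histogram.
#' Percentiles use the linear-interpolation convention. Variance, Skewness
#' and Kurtosis are population moments; for a zero-variance region Skewness
#' and Kurtosis are defined as 0 by convention so that downstream agreement
#' statistics always receive numbers. Kurtosis is uncorrected (a Gaussian has
#' Kurtosis 3). TotalEnergy scales Energy by the physical voxel volume.
#'
#' @param volume An [rr_volume()].
#' @param mask An [rr_mask()] aligned to `volume`.
#' @param bin_width Histogram bin width for Entropy/Uniformity.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(volume, mask, bin_width) {
  check_aligned(volume, mask)
  x <- volume$voxels[mask$voxels == 1L]
  n <- length(x)
  if (n < 1) stop("mask is empty")
  vv <- prod(volume$spacing)

  disc <- discretize(volume, mask, bin_width)
  p <- tabulate(disc$levels[disc$levels > 0L], nbins = disc$ng) / n
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  uniformity <- sum(p^2)

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  inner <- x[x >= q[1] & x <= q[5]]
  rmad <- if (length(inner) > 0) mean(abs(inner - mean(inner))) else 0

  c(Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = entropy,
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = uniformity)
}
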