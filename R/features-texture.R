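# Texture features over the five matrix families. Matrix counting is done in
# compiled code (src/textures.cpp); formulas live here. Texture matrices are
# built per direction where the family is directional (GLCM, GLRLM), each
# direction's features are computed separately and then averaged over the
# directions that contain at least one pair/run.
#
# Degenerate-region conventions (documented constants so that agreement
# statistics always receive numbers): on a single-gray-level region
# Correlation, Imc1, Imc2 and MCC are defined as 1 (perfectly dependent
# limit); NGTDM Coarseness is capped at 1e6 when its denominator vanishes;
# NGTDM Contrast/Busyness/Strength fall back to 0 when undefined.

glcm_feature_names <- function() c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC")

glcm_features_one <- function(C, ng) {
  N <- sum(C)
  if (N == 0) return(NULL)
  P <- C / N
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng)
  J <- t(I)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(iv * px)
  muy <- sum(iv * py)
  sigx2 <- sum((iv - mux)^2 * px)
  sigy2 <- sum((iv - muy)^2 * py)
  # diagonal-band distributions p_{|x-y|} and p_{x+y}
  kd <- 0:(ng - 1)
  pd <- numeric(ng)
  bd <- rowsum(as.vector(P), as.vector(abs(I - J)))
  pd[as.integer(rownames(bd)) + 1L] <- bd
  ks <- 2:(2 * ng)
  ps <- numeric(2 * ng - 1)
  bs <- rowsum(as.vector(P), as.vector(I + J))
  ps[as.integer(rownames(bs)) - 1L] <- bs
  occ <- which(px > 0)
  single <- length(occ) < 2L

  pl <- P[P > 0]
  hxy <- -sum(pl * log2(pl))
  lpxpy <- outer(px, py)
  selp <- P > 0 & lpxpy > 0
  hxy1 <- -sum(P[selp] * log2(lpxpy[selp]))
  sel2 <- lpxpy > 0
  hxy2 <- -sum(lpxpy[sel2] * log2(lpxpy[sel2]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))

  corr <- if (single || sigx2 <= 0 || sigy2 <= 0) 1 else
    (sum(P * I * J) - mux * muy) / sqrt(sigx2 * sigy2)
  imc1 <- if (single || max(hx, hy) <= 0) 1 else (hxy - hxy1) / max(hx, hy)
  imc2 <- if (single) 1 else sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  mcc <- if (single) 1 else {
    Po <- P[occ, occ, drop = FALSE]
    # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
    Q <- (Po / px[occ]) %*% t(sweep(Po, 2, py[occ], "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  }
  da <- sum(kd * pd)

  c(Autocorrelation = sum(P * I * J),
    JointAverage = mux,
    ClusterProminence = sum(P * (I + J - mux - muy)^4),
    ClusterShade = sum(P * (I + J - mux - muy)^3),
    ClusterTendency = sum(P * (I + J - mux - muy)^2),
    Contrast = sum(P * (I - J)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((kd - da)^2 * pd),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + (I - J)^2 / ng^2)),
    Id = sum(P / (1 + abs(I - J))),
    Idn = sum(P / (1 + abs(I - J) / ng)),
    InverseVariance = sum(P[I != J] / (I - J)[I != J]^2),
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sum(P * (I - mux)^2),
    MCC = mcc)
}

#' Gray-level co-occurrence features (24)
#'
#' Symmetric co-occurrence matrices over the 13 unique 3D directions at
#' Chebyshev offset `distance` (in voxels); features are computed per
#' direction and averaged over directions with at least one voxel pair.
#'
#' @param disc An [discretize()] result.
#' @param distance Pixel distance (voxels, >= 1).
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(disc, distance = 1L) {
  stopifnot(inherits(disc, "rr_discretized"))
  counts <- cpp_glcm(disc$levels, dim(disc$levels), disc$ng, as.integer(distance))
  per_dir <- lapply(1:13, function(d)
    glcm_features_one(matrix(counts[, , d], disc$ng, disc$ng), disc$ng))
  average_directions(per_dir, glcm_feature_names())
}

glrlm_feature_names <- function() c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

# shared size-gray weighted formulas for run-length (R: Ng x Lmax), size-zone
# and dependence matrices
size_matrix_features <- function(M, np, prefix = c("Run", "Zone")) {
  prefix <- match.arg(prefix)
  ns <- sum(M)
  iv <- seq_len(nrow(M))
  jv <- seq_len(ncol(M))
  p <- M / ns
  ri <- rowSums(M)
  cj <- colSums(M)
  mui <- sum(iv * rowSums(p))
  muj <- sum(jv * colSums(p))
  pl <- p[p > 0]
  W2i <- matrix(iv^2, nrow(M), ncol(M))
  W2j <- matrix(jv^2, nrow(M), ncol(M), byrow = TRUE)
  vals <- c(sum(M / W2j) / ns,
            sum(M * W2j) / ns,
            sum(ri^2) / ns,
            sum(ri^2) / ns^2,
            sum(cj^2) / ns,
            sum(cj^2) / ns^2,
            ns / np,
            sum(p * (matrix(iv, nrow(M), ncol(M)) - mui)^2),
            sum(p * (matrix(jv, nrow(M), ncol(M), byrow = TRUE) - muj)^2),
            -sum(pl * log2(pl)),
            sum(M / W2i) / ns,
            sum(M * W2i) / ns,
            sum(M / (W2i * W2j)) / ns,
            sum(M * W2i / W2j) / ns,
            sum(M * W2j / W2i) / ns,
            sum(M * W2i * W2j) / ns)
  names(vals) <- if (prefix == "Run") glrlm_feature_names() else glszm_feature_names()
  vals
}

#' Gray-level run-length features (16)
#'
#' Run-length matrices over the 13 unique 3D directions (unit offsets);
#' features computed per direction then averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(disc) {
  stopifnot(inherits(disc, "rr_discretized"))
  counts <- cpp_glrlm(disc$levels, dim(disc$levels), disc$ng)
  per_dir <- lapply(1:13, function(d) {
    M <- counts[, , d, drop = FALSE]
    dim(M) <- dim(counts)[1:2]
    if (sum(M) == 0) return(NULL)
    size_matrix_features(M, disc$n_voxels, "Run")
  })
  average_directions(per_dir, glrlm_feature_names())
}

glszm_feature_names <- function() c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

#' Gray-level size-zone features (16)
#'
#' Zones are 26-connected components of equal gray level (direction-free).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(disc) {
  stopifnot(inherits(disc, "rr_discretized"))
  zones <- cpp_glszm(disc$levels, dim(disc$levels))
  smax <- max(zones[, 2])
  M <- matrix(0, disc$ng, smax)
  for (r in seq_len(nrow(zones)))
    M[zones[r, 1], zones[r, 2]] <- M[zones[r, 1], zones[r, 2]] + 1
  size_matrix_features(M, disc$n_voxels, "Zone")
}

#' Neighbouring gray-tone difference features (5)
#'
#' For each gray level `i`, `s_i` sums the absolute difference between `i`
#' and the mean level of the valid (in-region) neighbours within Chebyshev
#' radius `distance`, over region voxels of level `i` that have at least one
#' valid neighbour; `n_i` counts those voxels.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(disc, distance = 1L) {
  stopifnot(inherits(disc, "rr_discretized"))
  sn <- cpp_ngtdm(disc$levels, dim(disc$levels), disc$ng, as.integer(distance))
  s <- sn[, 1]
  nv <- sn[, 2]
  Nv <- sum(nv)
  p <- nv / Nv
  occ <- which(p > 0)
  ngp <- length(occ)
  iv <- seq_len(disc$ng)

  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  if (ngp > 1) {
    IP <- outer(iv[occ], iv[occ], function(a, b) (a - b)^2)
    PP <- outer(p[occ], p[occ])
    contrast <- sum(PP * IP) / (ngp * (ngp - 1)) * sum(s) / Nv
    bden <- sum(abs(outer(iv[occ] * p[occ], iv[occ] * p[occ], "-")))
    busyness <- if (bden > 0) sum(p * s) / bden else 0
    AD <- abs(outer(iv[occ], iv[occ], "-"))
    PS <- outer(p[occ] * s[occ], p[occ] * s[occ], "+")
    PSUM <- outer(p[occ], p[occ], "+")
    complexity <- sum(AD * PS / PSUM) / Nv
    sden <- sum(s)
    strength <- if (sden > 0) sum(PSUM * IP) / sden else 0
  } else {
    contrast <- 0
    busyness <- 0
    complexity <- 0
    strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

gldm_feature_names <- function() c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

#' Gray-level dependence features (14)
#'
#' The dependence of a region voxel is the number of neighbours within
#' Chebyshev radius `distance` whose gray level differs by at most `alpha`
#' (default 0). Matrix column `j` corresponds to dependence `j - 1`, i.e.
#' emphasis weights use dependence + 1, so isolated voxels stay defined.
#'
#' @inheritParams glcm_features
#' @param alpha Gray-level difference tolerance (default 0).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(disc, distance = 1L, alpha = 0L) {
  stopifnot(inherits(disc, "rr_discretized"))
  D <- cpp_gldm(disc$levels, dim(disc$levels), disc$ng, as.integer(distance),
                as.integer(alpha))
  # drop trailing all-zero dependence columns (keeps weights j = dep + 1)
  nzc <- which(colSums(D) > 0)
  D <- D[, seq_len(max(nzc)), drop = FALSE]
  ns <- sum(D)
  iv <- seq_len(nrow(D))
  jv <- seq_len(ncol(D))
  p <- D / ns
  ri <- rowSums(D)
  cj <- colSums(D)
  mui <- sum(iv * rowSums(p))
  muj <- sum(jv * colSums(p))
  pl <- p[p > 0]
  W2i <- matrix(iv^2, nrow(D), ncol(D))
  W2j <- matrix(jv^2, nrow(D), ncol(D), byrow = TRUE)
  c(SmallDependenceEmphasis = sum(D / W2j) / ns,
    LargeDependenceEmphasis = sum(D * W2j) / ns,
    GrayLevelNonUniformity = sum(ri^2) / ns,
    DependenceNonUniformity = sum(cj^2) / ns,
    DependenceNonUniformityNormalized = sum(cj^2) / ns^2,
    GrayLevelVariance = sum(p * (matrix(iv, nrow(D), ncol(D)) - mui)^2),
    DependenceVariance = sum(p * (matrix(jv, nrow(D), ncol(D), byrow = TRUE) - muj)^2),
    DependenceEntropy = -sum(pl * log2(pl)),
    LowGrayLevelEmphasis = sum(D / W2i) / ns,
    HighGrayLevelEmphasis = sum(D * W2i) / ns,
    SmallDependenceLowGrayLevelEmphasis = sum(D / (W2i * W2j)) / ns,
    SmallDependenceHighGrayLevelEmphasis = sum(D * W2i / W2j) / ns,
    LargeDependenceLowGrayLevelEmphasis = sum(D * W2j / W2i) / ns,
    LargeDependenceHighGrayLevelEmphasis = sum(D * W2i * W2j) / ns)
}

# average per-direction feature vectors, skipping directions with no pairs;
# all-empty -> NA vector
average_directions <- function(per_dir, nms) {
  keep <- Filter(Negate(is.null), per_dir)
  if (length(keep) == 0L) {
    out <- rep(NA_real_, length(nms))
    names(out) <- nms
    return(out)
  }
  colMeans(do.call(rbind, keep))
}
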