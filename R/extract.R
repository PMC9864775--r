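WAVELET_BANDS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
INTENSITY_FAMILIES <- c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm")
ALL_FILTERS <- c("original", paste0("wavelet-", WAVELET_BANDS))

family_feature_names <- function(family) {
  switch(family,
         shape = names(shape_features(rr_mask(array(1L, c(2, 2, 2)), c(1, 1, 1)))),
         firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                        "10Percentile", "90Percentile", "Maximum", "Mean",
                        "Median", "InterquartileRange", "Range",
                        "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                        "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                        "Uniformity"),
         glcm = glcm_feature_names(),
         glrlm = glrlm_feature_names(),
         glszm = glszm_feature_names(),
         ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity",
                   "Strength"),
         gldm = gldm_feature_names(),
         stop("unknown family: ", family))
}

#' Canonical feature names in extraction order
#'
#' The full set has 851 names: 107 from the original image (the six intensity
#' families, 93 features, followed by the 14 shape features) and 93 intensity
#' features on each of the eight wavelet sub-bands. Names follow the
#' `<filter>_<family>_<name>` convention, e.g. `original_shape_Sphericity`,
#' `wavelet-HLH_glcm_Contrast`.
#'
#' @param filters Subset of `"original"`, `"wavelet-LLL"`, ..., default all.
#' @param families Subset of `"shape"`, `"firstorder"`, `"glcm"`, `"glrlm"`,
#'   `"glszm"`, `"ngtdm"`, `"gldm"`; default all.
#' @return Character vector of feature names in stable order.
#' @export
feature_names <- function(filters = ALL_FILTERS,
                          families = c("shape", INTENSITY_FAMILIES)) {
  filters <- match.arg(filters, ALL_FILTERS, several.ok = TRUE)
  families <- match.arg(families, c("shape", INTENSITY_FAMILIES),
                        several.ok = TRUE)
  out <- character(0)
  if ("original" %in% filters) {
    for (fam in intersect(INTENSITY_FAMILIES, families))
      out <- c(out, paste0("original_", fam, "_", family_feature_names(fam)))
    if ("shape" %in% families)
      out <- c(out, paste0("original_shape_", family_feature_names("shape")))
  }
  for (b in WAVELET_BANDS) {
    f <- paste0("wavelet-", b)
    if (!(f %in% filters)) next
    for (fam in intersect(INTENSITY_FAMILIES, families))
      out <- c(out, paste0(f, "_", fam, "_", family_feature_names(fam)))
  }
  out
}

# 93 intensity features of one image
intensity_features_one <- function(volume, mask, config, families) {
  out <- numeric(0)
  disc <- NULL
  need_disc <- any(c("glcm", "glrlm", "glszm", "ngtdm", "gldm") %in% families)
  if (need_disc) disc <- discretize(volume, mask, config$bin_width)
  for (fam in intersect(INTENSITY_FAMILIES, families)) {
    v <- switch(fam,
                firstorder = first_order_features(volume, mask, config$bin_width),
                glcm = glcm_features(disc, config$pixel_distance),
                glrlm = glrlm_features(disc),
                glszm = glszm_features(disc),
                ngtdm = ngtdm_features(disc, config$pixel_distance),
                gldm = gldm_features(disc, config$pixel_distance))
    names(v) <- paste0(fam, "_", names(v))
    out <- c(out, v)
  }
  out
}

#' Extract the full radiomic feature vector
#'
#' Runs the preprocessing chain for one grid point -- resample volume and
#' mask to isotropic resolution with the configured interpolator, compute the
#' eight coif1 wavelet sub-bands of the resampled volume, discretize each
#' image at the configured bin width (re-anchored per sub-band) -- and
#' computes the intensity/texture families on the original image and every
#' sub-band, plus the 14 shape features from the resampled mask geometry. A
#' full extraction returns exactly 851 named values in stable order; shape
#' values are identical across bin widths and pixel distances by
#' construction.
#'
#' @param volume An [rr_volume()].
#' @param mask An [rr_mask()] aligned to `volume`.
#' @param config An [extraction_config()].
#' @param filters,families Optional subsets (see [feature_names()]) to
#'   restrict computation, e.g. `filters = "original"` skips the wavelet
#'   transform entirely.
#' @return Named numeric vector (length 851 for a full extraction).
#' @examples
#' spec <- phantom_spec(seed = 3, noise_sd = 5, grid_shape = c(32, 32, 24),
#'                      lesion_radii = c(6, 6, 6))
#' vol <- generate_phantom(spec)
#' msk <- generate_segmentation(spec, "accurate")
#' fv <- extract_features(vol, msk, extraction_config(), filters = "original")
#' length(fv)
#' @export
extract_features <- function(volume, mask, config = extraction_config(),
                             filters = ALL_FILTERS,
                             families = c("shape", INTENSITY_FAMILIES)) {
  stopifnot(inherits(config, "rr_config"))
  filters <- match.arg(filters, ALL_FILTERS, several.ok = TRUE)
  families <- match.arg(families, c("shape", INTENSITY_FAMILIES),
                        several.ok = TRUE)
  rs <- resample_volume(volume, mask, config$resolution_mm, config$interpolator)
  out <- numeric(0)
  int_fams <- intersect(INTENSITY_FAMILIES, families)
  if ("original" %in% filters) {
    v <- if (length(int_fams))
      intensity_features_one(rs$volume, rs$mask, config, int_fams) else numeric(0)
    if (length(v)) names(v) <- paste0("original_", names(v))
    out <- c(out, v)
    if ("shape" %in% families) {
      sv <- shape_features(rs$mask)
      names(sv) <- paste0("original_shape_", names(sv))
      out <- c(out, sv)
    }
  }
  wfilters <- intersect(paste0("wavelet-", WAVELET_BANDS), filters)
  if (length(wfilters) > 0 && length(int_fams) > 0) {
    bands <- wavelet_decompose(rs$volume)
    for (f in wfilters) {
      b <- sub("^wavelet-", "", f)
      v <- intensity_features_one(bands[[b]], rs$mask, config, int_fams)
      names(v) <- paste0(f, "_", names(v))
      out <- c(out, v)
    }
  }
  out
}
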