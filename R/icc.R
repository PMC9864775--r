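#' Intraclass correlation: two-way random effects, absolute agreement,
#' single measure
#'
#' Agreement across segmentation styles is scored with ICC(A,1) in the
#' McGraw--Wong nomenclature: subjects (patients) and raters (segmentation
#' styles) are both treated as random effects and systematic offsets between
#' raters are penalised. From the two-way ANOVA mean squares (rows `MSR`,
#' columns `MSC`, error `MSE`),
#' `icc = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`,
#' and the 95% confidence interval uses the standard F-based construction
#' with Satterthwaite degrees of freedom.
#'
#' @param ratings Numeric matrix, subjects in rows (`n >= 2`), raters in
#'   columns (`k >= 2`), no missing values.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return An object of class `rr_icc`: fields `icc`, `ci_lower`, `ci_upper`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `conf_level`,
#'   `model_label`.
#' @examples
#' m <- cbind(1:6, 1:6 + 0.2, 1:6 - 0.1)
#' icc_agreement(m)
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (any(!is.finite(ratings))) stop("ratings contain non-finite values")
  if (max(ratings) - min(ratings) == 0)
    stop("all ratings identical: agreement is undefined")

  gm <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm_ <- colMeans(ratings)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm_ - gm)^2)
  sse <- sum((ratings - outer(rm_, cm_, "+") + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # columns reproduce each subject exactly: perfect absolute agreement
    lb <- ub <- 1
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lb <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ub <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  structure(list(icc = icc, ci_lower = lb, ci_upper = ub,
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k, conf_level = conf_level,
                 model_label = "two-way random, absolute agreement, single measure (A,1)"),
            class = "rr_icc")
}

#' @export
print.rr_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f, %d%% CI [%.4f, %.4f]  (n = %d subjects, k = %d raters)\n",
              x$icc, round(100 * x$conf_level), x$ci_lower, x$ci_upper, x$n, x$k))
  invisible(x)
}

#' Per-feature ICC across segmentations
#'
#' For each (configuration, feature) cell of a long feature table, builds the
#' patients x segmentations ratings matrix and computes [icc_agreement()].
#' A feature is flagged `excellent` when the lower bound of the 95%
#' confidence interval strictly exceeds `threshold` (default 0.9). Features
#' with missing or non-finite cells, or with all values identical, are
#' skipped for that configuration and listed in the `skipped` attribute.
#'
#' @param feature_table Data frame with columns `patient_id`,
#'   `segmentation`, `config_id`, `feature`, `value` (see
#'   [extract_cohort()]).
#' @param threshold Excellence threshold on the CI lower bound.
#' @return Data frame, class `rr_icc_table`, with one row per (config_id,
#'   feature): `icc`, `ci_lower`, `ci_upper`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `model`, `excellent`.
#' @export
robustness_table <- function(feature_table, threshold = 0.9) {
  req <- c("patient_id", "segmentation", "config_id", "feature", "value")
  if (!all(req %in% names(feature_table)))
    stop("feature_table must have columns ", paste(req, collapse = ", "))
  segs <- sort(unique(feature_table$segmentation))
  pats <- sort(unique(feature_table$patient_id))
  rows <- list()
  skipped <- character(0)
  for (cid in unique(feature_table$config_id)) {
    sub <- feature_table[feature_table$config_id == cid, ]
    for (feat in unique(sub$feature)) {
      fs <- sub[sub$feature == feat, ]
      m <- matrix(NA_real_, length(pats), length(segs),
                  dimnames = list(pats, segs))
      m[cbind(match(fs$patient_id, pats), match(fs$segmentation, segs))] <- fs$value
      if (any(!is.finite(m))) {
        skipped <- c(skipped, sprintf("%s | %s: missing or non-finite cells", cid, feat))
        next
      }
      if (max(m) - min(m) == 0) {
        skipped <- c(skipped, sprintf("%s | %s: all values identical", cid, feat))
        next
      }
      r <- icc_agreement(m)
      rows[[length(rows) + 1L]] <-
        data.frame(config_id = cid, feature = feat, icc = r$icc,
                   ci_lower = r$ci_lower, ci_upper = r$ci_upper,
                   ms_rows = r$ms_rows, ms_cols = r$ms_cols,
                   ms_error = r$ms_error, model = r$model_label,
                   excellent = r$ci_lower > threshold,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(config_id = character(), feature = character(),
                      icc = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), ms_rows = numeric(),
                      ms_cols = numeric(), ms_error = numeric(),
                      model = character(), excellent = logical(),
                      stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  class(out) <- c("rr_icc_table", class(out))
  out
}

#' Sensitivity of the ICC lower bound to one preprocessing parameter
#'
#' For each feature and each varied parameter, the configurations are grouped
#' by the values of the three remaining parameters; within each group the
#' range (max - min) of the ICC 95% CI lower bound across the varied
#' parameter's values is taken, and the worst case (maximum range over
#' groups) is reported. A range below `low_threshold` (default 0.1) counts as
#' low sensitivity. Requires a complete factorial grid.
#'
#' @param icc_table An [robustness_table()] result.
#' @param grid_info Data frame mapping `config_id` to `bin_width`,
#'   `pixel_distance`, `interpolator`, `resolution_mm` (see
#'   [config_grid_info()]).
#' @param parameter One of `"bin_width"`, `"pixel_distance"`,
#'   `"interpolator"`, `"resolution_mm"`.
#' @param low_threshold Low-sensitivity threshold on the range.
#' @return Data frame with one row per feature: `feature`, `parameter`,
#'   `icc_range`, `is_low`.
#' @export
sensitivity_range <- function(icc_table, grid_info,
                              parameter = c("bin_width", "pixel_distance",
                                            "interpolator", "resolution_mm"),
                              low_threshold = 0.1) {
  parameter <- match.arg(parameter)
  tab <- merge(as.data.frame(icc_table)[, c("config_id", "feature", "ci_lower")],
               grid_info, by = "config_id")
  others <- setdiff(c("bin_width", "pixel_distance", "interpolator",
                      "resolution_mm"), parameter)
  nvar <- length(unique(grid_info[[parameter]]))
  rows <- list()
  for (feat in unique(tab$feature)) {
    fs <- tab[tab$feature == feat, ]
    key <- interaction(fs[others], drop = TRUE)
    full <- tapply(fs$ci_lower, key, length)
    if (any(full != nvar)) {
      miss <- names(full)[full != nvar]
      stop(sprintf("incomplete grid for feature '%s', parameter '%s': fixed-parameter cells %s lack some values",
                   feat, parameter, paste(miss, collapse = "; ")))
    }
    rng <- tapply(fs$ci_lower, key, function(v) max(v) - min(v))
    rows[[length(rows) + 1L]] <-
      data.frame(feature = feat, parameter = parameter,
                 icc_range = max(rng), is_low = max(rng) < low_threshold,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Coefficient of variation across one patient's segmentations
#'
#' `cv = sample SD / mean` of the feature values over the patient's
#' segmentations. Features like cluster shade can be legitimately negative,
#' so the absolute mean is used in the denominator; when the absolute mean is
#' below `eps` the record is flagged excluded rather than producing an
#' unstable ratio.
#'
#' @param values Numeric vector (the 3 segmentation values).
#' @param eps Exclusion threshold on the absolute mean (callers pass
#'   `1e-8 * cohort feature scale`).
#' @return List with `cv` and logical `excluded`.
#' @examples
#' cv_per_patient(c(8, 10, 12))$cv  # 0.2
#' @export
cv_per_patient <- function(values, eps = 1e-12) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) return(list(cv = NA_real_, excluded = TRUE))
  m <- mean(values)
  if (abs(m) < eps) return(list(cv = NA_real_, excluded = TRUE))
  list(cv = stats::sd(values) / abs(m), excluded = FALSE)
}

#' Per-feature CV table at one configuration
#'
#' @param feature_table Long feature table (see [robustness_table()]).
#' @param config_id Configuration to use.
#' @return Data frame `feature`, `patient_id`, `cv`, `excluded`; the
#'   exclusion threshold per feature is `1e-8` times the feature's maximum
#'   absolute value in the cohort.
#' @export
cv_table <- function(feature_table, config_id) {
  sub <- feature_table[feature_table$config_id == config_id, ]
  if (nrow(sub) == 0) stop("no rows for config_id ", config_id)
  rows <- list()
  for (feat in unique(sub$feature)) {
    fs <- sub[sub$feature == feat, ]
    scale <- max(abs(fs$value[is.finite(fs$value)]), 0)
    eps <- 1e-8 * max(scale, .Machine$double.eps)
    for (pid in unique(fs$patient_id)) {
      v <- fs$value[fs$patient_id == pid]
      r <- cv_per_patient(v, eps)
      rows[[length(rows) + 1L]] <-
        data.frame(feature = feat, patient_id = pid, cv = r$cv,
                   excluded = r$excluded, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Spearman correlation between per-patient CV and lesion size
#'
#' For each feature, the Spearman rank correlation (mid-ranks for ties)
#' between the per-patient coefficient of variation and the per-patient
#' lesion volume (VoxelVolume of the accurate segmentation). Features with
#' fewer than 3 usable (non-excluded) patients are skipped and listed in the
#' `skipped` attribute.
#'
#' @param cv_tab A [cv_table()] result.
#' @param volumes Named numeric vector of lesion volumes, names = patient
#'   ids.
#' @return Data frame `feature`, `rho`, `n_used`.
#' @export
cv_size_correlation <- function(cv_tab, volumes) {
  rows <- list()
  skipped <- character(0)
  for (feat in unique(cv_tab$feature)) {
    fs <- cv_tab[cv_tab$feature == feat & !cv_tab$excluded, ]
    fs <- fs[fs$patient_id %in% names(volumes), ]
    if (nrow(fs) < 3) {
      skipped <- c(skipped, sprintf("%s: only %d usable patients", feat, nrow(fs)))
      next
    }
    if (stats::sd(fs$cv) == 0 || stats::sd(volumes[fs$patient_id]) == 0) {
      skipped <- c(skipped, sprintf("%s: zero variance, correlation undefined", feat))
      next
    }
    rho <- stats::cor(fs$cv, volumes[fs$patient_id], method = "spearman")
    rows[[length(rows) + 1L]] <-
      data.frame(feature = feat, rho = rho, n_used = nrow(fs),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(), rho = numeric(),
                      n_used = integer(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
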