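#' Map a configuration grid to a parameter table
#'
#' @param configs A list of [extraction_config()] objects.
#' @return Data frame `config_id`, `bin_width`, `pixel_distance`,
#'   `interpolator`, `resolution_mm`.
#' @export
config_grid_info <- function(configs) {
  do.call(rbind, lapply(configs, function(cf)
    data.frame(config_id = cf$id, bin_width = cf$bin_width,
               pixel_distance = cf$pixel_distance,
               interpolator = cf$interpolator,
               resolution_mm = cf$resolution_mm, stringsAsFactors = FALSE)))
}

#' Extract features for a whole cohort over a configuration grid
#'
#' @param cohort An `rr_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param configs List of [extraction_config()] objects.
#' @param filters,families Optional restriction, see [feature_names()].
#' @return Long data frame (`FeatureTable`): `patient_id`, `segmentation`,
#'   `config_id`, `feature`, `value`; exactly one row per key.
#' @export
extract_cohort <- function(cohort, configs = list(extraction_config()),
                           filters = ALL_FILTERS,
                           families = c("shape", INTENSITY_FAMILIES)) {
  if (inherits(configs, "rr_config")) configs <- list(configs)
  rows <- vector("list", length(cohort) * 3L * length(configs))
  ri <- 0L
  for (p in cohort) {
    for (s in segmentation_styles()) {
      for (cf in configs) {
        fv <- extract_features(p$volume, p$masks[[s]], cf,
                               filters = filters, families = families)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(patient_id = p$id, segmentation = s,
                                 config_id = cf$id, feature = names(fv),
                                 value = unname(fv), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the cohort source (synthetic
#' generator settings, or a directory to read), the preprocessing grid, the
#' robustness thresholds, and the output directory.
#'
#' @param out_dir Output directory for all CSV artifacts.
#' @param n_patients,master_seed,ranges Synthetic-cohort settings (ignored
#'   when `cohort_dir` is given).
#' @param cohort_dir Optional directory with an existing cohort
#'   (`manifest.csv` + images).
#' @param grid List of [extraction_config()]s; default the full 81-point
#'   study grid.
#' @param filters,families Optional feature restriction (see
#'   [feature_names()]).
#' @param icc_excellent,sensitivity_low Robustness thresholds.
#' @param reference_config_id Configuration at which the CV/lesion-size
#'   analysis is done; default the grid's first configuration.
#' @param write_images If `TRUE`, also write the cohort volumes/masks under
#'   `out_dir/cohort` (the manifest is always written).
#' @return List of class `rr_experiment`.
#' @export
experiment_config <- function(out_dir,
                              n_patients = 48L, master_seed = 1L,
                              ranges = cohort_ranges(),
                              cohort_dir = NULL,
                              grid = config_grid(),
                              filters = ALL_FILTERS,
                              families = c("shape", INTENSITY_FAMILIES),
                              icc_excellent = 0.9, sensitivity_low = 0.1,
                              reference_config_id = NULL,
                              write_images = FALSE) {
  if (length(grid) == 0) stop("empty configuration grid")
  if (icc_excellent <= 0 || icc_excellent >= 1) stop("'icc_excellent' must be in (0,1)")
  if (sensitivity_low <= 0 || sensitivity_low >= 1) stop("'sensitivity_low' must be in (0,1)")
  if (is.null(reference_config_id)) reference_config_id <- grid[[1]]$id
  structure(list(out_dir = out_dir, n_patients = as.integer(n_patients),
                 master_seed = as.integer(master_seed), ranges = ranges,
                 cohort_dir = cohort_dir, grid = grid, filters = filters,
                 families = families, icc_excellent = icc_excellent,
                 sensitivity_low = sensitivity_low,
                 reference_config_id = reference_config_id,
                 write_images = write_images),
            class = "rr_experiment")
}

#' Run the full robustness experiment
#'
#' Cohort (generated or loaded) -> feature extraction over the configuration
#' grid (one CSV per configuration, resumable) -> per-feature ICC table ->
#' per-parameter sensitivity table -> CV/lesion-size correlation table, plus
#' a manifest and a run log. Deterministic given the master seed: re-running
#' with the same configuration reproduces all numeric outputs.
#'
#' @param exp An [experiment_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the output paths and the in-memory tables
#'   (`feature_table`, `icc_table`, `sensitivity`, `cv_correlation`).
#' @export
run_experiment <- function(exp, quiet = FALSE) {
  stopifnot(inherits(exp, "rr_experiment"))
  dir.create(exp$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  log_lines <- c(sprintf("radiorobust %s", as.character(utils::packageVersion("radiorobust"))),
                 sprintf("master_seed: %d", exp$master_seed),
                 sprintf("grid: %d configurations", length(exp$grid)))

  if (!is.null(exp$cohort_dir)) {
    say("reading cohort from %s", exp$cohort_dir)
    cohort <- read_cohort(exp$cohort_dir)
  } else {
    say("generating synthetic cohort: %d patients, seed %d",
        exp$n_patients, exp$master_seed)
    cohort <- generate_cohort(exp$n_patients, exp$master_seed, exp$ranges)
  }
  if (exp$write_images && is.null(exp$cohort_dir)) {
    write_cohort(cohort, file.path(exp$out_dir, "cohort"))
  } else {
    # manifest only
    manifest <- do.call(rbind, lapply(cohort, function(p)
      data.frame(patient_id = p$id,
                 seed = if (!is.null(p$spec$seed)) p$spec$seed else NA,
                 n_voxels_accurate = sum(p$masks$accurate$voxels),
                 stringsAsFactors = FALSE)))
    utils::write.csv(manifest, file.path(exp$out_dir, "manifest.csv"),
                     row.names = FALSE)
  }

  expected_rows <- length(cohort) * 3L *
    length(feature_names(exp$filters, exp$families))
  tables <- list()
  for (cf in exp$grid) {
    fpath <- file.path(exp$out_dir, sprintf("features_%s.csv", cf$id))
    if (file.exists(fpath)) {
      tab <- tryCatch(utils::read.csv(fpath, stringsAsFactors = FALSE),
                      error = function(e) NULL)
      if (!is.null(tab) && nrow(tab) == expected_rows &&
          all(c("patient_id", "segmentation", "config_id", "feature", "value") %in% names(tab))) {
        say("config %s: resuming from existing file", cf$id)
        tables[[cf$id]] <- tab
        next
      }
      stop("corrupt intermediate file: ", fpath,
           " (delete it to recompute this configuration)")
    }
    say("config %s: extracting", cf$id)
    tab <- extract_cohort(cohort, list(cf), exp$filters, exp$families)
    utils::write.csv(tab, fpath, row.names = FALSE)
    tables[[cf$id]] <- tab
  }
  feature_table <- do.call(rbind, tables)
  rownames(feature_table) <- NULL

  say("computing ICC table")
  icc_tab <- robustness_table(feature_table, exp$icc_excellent)
  utils::write.csv(as.data.frame(icc_tab), file.path(exp$out_dir, "icc_table.csv"),
                   row.names = FALSE)

  say("computing sensitivity table")
  gi <- config_grid_info(exp$grid)
  sens <- do.call(rbind, lapply(
    c("bin_width", "pixel_distance", "interpolator", "resolution_mm"),
    function(p) sensitivity_range(icc_tab, gi, p, exp$sensitivity_low)))
  utils::write.csv(sens, file.path(exp$out_dir, "sensitivity.csv"),
                   row.names = FALSE)

  say("computing CV / lesion-size correlation")
  vols <- vapply(cohort, function(p)
    sum(p$masks$accurate$voxels) * prod(p$masks$accurate$spacing), 0)
  names(vols) <- vapply(cohort, `[[`, "", "id")
  cvt <- cv_table(feature_table, exp$reference_config_id)
  cvc <- cv_size_correlation(cvt, vols)
  utils::write.csv(cvc, file.path(exp$out_dir, "cv_correlation.csv"),
                   row.names = FALSE)

  log_lines <- c(log_lines,
                 sprintf("patients: %d", length(cohort)),
                 sprintf("feature rows: %d", nrow(feature_table)),
                 sprintf("icc rows: %d", nrow(icc_tab)),
                 sprintf("skipped icc cells: %d", length(attr(icc_tab, "skipped"))),
                 sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, file.path(exp$out_dir, "run_log.txt"))

  invisible(list(out_dir = exp$out_dir, feature_table = feature_table,
                 icc_table = icc_tab, sensitivity = sens,
                 cv_correlation = cvc, cohort = cohort))
}
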