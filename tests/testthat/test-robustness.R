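# robustness_table and sensitivity_range on crafted feature tables

mk_feature_table <- function(values, feature = "f", config = "c1",
                             segs = c("accurate", "rough_freehand", "rough_polygon")) {
  # values: patients x 3 matrix
  n <- nrow(values)
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(patient_id = sprintf("P%02d", i), segmentation = segs,
               config_id = config, feature = feature, value = values[i, ],
               stringsAsFactors = FALSE)))
}

test_that("a feature constant within patient but varying across patients is excellent", {
  m <- matrix(rep(c(1, 5, 9, 13), 3), ncol = 3)
  tab <- robustness_table(mk_feature_table(m))
  expect_equal(tab$icc, 1)
  expect_true(tab$excellent)
  expect_match(tab$model, "absolute agreement")
})

test_that("pure-noise features are not excellent; threshold uses strict inequality", {
  set.seed(5)
  m <- matrix(rnorm(48 * 3), 48, 3)
  tab <- robustness_table(mk_feature_table(m))
  expect_lt(abs(tab$icc), 0.35)
  expect_false(tab$excellent)
  # boundary: a lower bound exactly at the threshold must NOT be excellent
  set.seed(6)
  m2 <- matrix(rnorm(20 * 3), 20, 3) + rnorm(20, sd = 4)
  tab2 <- robustness_table(mk_feature_table(m2))
  tab2b <- robustness_table(mk_feature_table(m2), threshold = tab2$ci_lower)
  expect_false(tab2b$excellent)
})

test_that("missing and degenerate cells are skipped with a log entry", {
  m <- matrix(rep(c(1, 5, 9, 13), 3), ncol = 3)
  ft <- mk_feature_table(m)
  ft <- ft[-2, ]  # drop one cell
  tab <- robustness_table(ft)
  expect_equal(nrow(tab), 0)
  expect_length(attr(tab, "skipped"), 1)
  expect_match(attr(tab, "skipped"), "missing")

  ft2 <- mk_feature_table(matrix(7, 4, 3))
  tab2 <- robustness_table(ft2)
  expect_match(attr(tab2, "skipped"), "identical")
})

test_that("sensitivity range is the worst-case span over fixed-parameter groups", {
  grid <- expand.grid(bin_width = c(10, 20, 40), pixel_distance = 1,
                      interpolator = "linear", resolution_mm = 2,
                      stringsAsFactors = FALSE)
  grid$config_id <- sprintf("c%d", seq_len(nrow(grid)))
  icc_tab <- data.frame(config_id = grid$config_id, feature = "f",
                        ci_lower = c(0.91, 0.93, 0.92))
  out <- sensitivity_range(icc_tab, grid, "bin_width")
  expect_equal(out$icc_range, 0.02)
  expect_true(out$is_low)

  icc_tab$ci_lower <- c(0.95, 0.80, 0.92)
  out <- sensitivity_range(icc_tab, grid, "bin_width")
  expect_equal(out$icc_range, 0.15)
  expect_false(out$is_low)

  icc_tab$ci_lower <- rep(0.7, 3)
  for (p in c("bin_width", "pixel_distance", "interpolator", "resolution_mm"))
    expect_equal(sensitivity_range(icc_tab, grid, p)$icc_range, 0)

  # worst case across groups: two resolutions, ranges 0.02 and 0.2
  grid2 <- expand.grid(bin_width = c(10, 20), pixel_distance = 1,
                       interpolator = "linear", resolution_mm = c(1, 2),
                       stringsAsFactors = FALSE)
  grid2$config_id <- sprintf("g%d", seq_len(nrow(grid2)))
  icc2 <- data.frame(config_id = grid2$config_id, feature = "f",
                     ci_lower = c(0.90, 0.92, 0.70, 0.90))
  out2 <- sensitivity_range(icc2, grid2, "bin_width")
  expect_equal(out2$icc_range, 0.2)

  # incomplete grid errors, naming the gap
  expect_error(sensitivity_range(icc2[-1, ], grid2, "bin_width"), "incomplete")
})
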