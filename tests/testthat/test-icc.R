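# ICC(A,1) agreement statistic and CV records

test_that("identical columns give perfect agreement", {
  m <- cbind(1:6, 1:6, 1:6)
  r <- icc_agreement(m)
  expect_equal(r$icc, 1)
  expect_equal(r$ci_upper, 1)
  expect_equal(r$ci_lower, 1)
})

test_that("additive rater offsets are penalised; ANOVA matches the hand-computed layout", {
  # x_ij = r_i + c_j with r = (0,2,4,6), c = (0,1,2):
  # MSR = 20, MSC = 4, MSE = 0, ICC = 20 / 23
  m <- outer(c(0, 2, 4, 6), c(0, 1, 2), "+")
  r <- icc_agreement(m)
  expect_equal(r$ms_rows, 20)
  expect_equal(r$ms_cols, 4)
  expect_equal(r$ms_error, 0)
  expect_equal(r$icc, 20 / 23)
  expect_lt(r$icc, 1)
  o <- o_icc(m)
  expect_equal(r$icc, o$icc, tolerance = 1e-12)
  expect_equal(r$ci_lower, o$lb, tolerance = 1e-12)
  expect_equal(r$ci_upper, o$ub, tolerance = 1e-12)
})

test_that("implementation matches the brute-force ANOVA oracle on random matrices", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = sample(1:10, 1)), n, k) +
      rnorm(n, sd = 3)           # subject effect
    r <- icc_agreement(m)
    o <- o_icc(m)
    expect_equal(r$icc, o$icc, tolerance = 1e-12)
    expect_equal(r$ci_lower, o$lb, tolerance = 1e-12)
    expect_equal(r$ci_upper, o$ub, tolerance = 1e-12)
    expect_lte(r$ci_lower, r$icc)
    expect_gte(r$ci_upper, r$icc)
    expect_lte(r$icc, 1)
  }
})

test_that("single simulation at generative ICC 0.9 lands near 0.9", {
  set.seed(7)
  n <- 200
  subj <- rnorm(n, sd = 3)
  m <- subj + matrix(rnorm(n * 3, sd = 1), n, 3)
  r <- icc_agreement(m)
  expect_lt(abs(r$icc - 0.9), 0.05)
})

test_that("ICC is invariant to row/column permutation and location, scales with positive factors", {
  set.seed(17)
  m <- matrix(rnorm(30), 10, 3) + rnorm(10, sd = 2)
  r <- icc_agreement(m)
  expect_equal(icc_agreement(m[sample(10), ])$icc, r$icc, tolerance = 1e-12)
  expect_equal(icc_agreement(m[, c(3, 1, 2)])$icc, r$icc, tolerance = 1e-12)
  expect_equal(icc_agreement(m + 100)$icc, r$icc, tolerance = 1e-12)
  expect_equal(icc_agreement(m * 3.7)$icc, r$icc, tolerance = 1e-12)
})

test_that("confidence interval tightens as n grows", {
  widths <- vapply(c(10, 40, 160), function(n) {
    set.seed(n)
    m <- rnorm(n, sd = 3) + matrix(rnorm(n * 3), n, 3)
    r <- icc_agreement(m)
    r$icc - r$ci_lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("degenerate ratings are rejected", {
  expect_error(icc_agreement(matrix(5, 4, 3)), "identical")
  expect_error(icc_agreement(matrix(1:3, 1, 3)), "at least 2")
  expect_error(icc_agreement(cbind(1:5)), "at least 2")
  expect_error(icc_agreement(cbind(1:4, c(1, 2, NA, 4))), "non-finite")
})

test_that("coefficient of variation follows its definition with the near-zero-mean guard", {
  expect_equal(cv_per_patient(c(10, 10, 10))$cv, 0)
  r <- cv_per_patient(c(8, 10, 12))
  expect_equal(r$cv, 0.2)
  expect_false(r$excluded)
  r0 <- cv_per_patient(c(-5, 0, 5))
  expect_true(r0$excluded)
  expect_true(is.na(r0$cv))
  # negative mean uses |mean|
  rn <- cv_per_patient(c(-8, -10, -12))
  expect_equal(rn$cv, 0.2)
})

test_that("Spearman correlation of CV vs size handles monotone, null and tied cases", {
  cvt <- data.frame(feature = "f", patient_id = paste0("P", 1:6),
                    cv = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1), excluded = FALSE)
  vols <- setNames(c(10, 20, 30, 40, 50, 60), paste0("P", 1:6))
  out <- cv_size_correlation(cvt, vols)
  expect_equal(out$rho, -1)

  # duplicated volumes: mid-rank brute-force oracle
  vols2 <- setNames(c(10, 10, 30, 30, 50, 60), paste0("P", 1:6))
  set.seed(3)
  cvt$cv <- runif(6)
  out2 <- cv_size_correlation(cvt, vols2)
  midrank <- function(x) {
    sapply(seq_along(x), function(i)
      sum(x < x[i]) + (1 + sum(x == x[i])) / 2)
  }
  rx <- midrank(cvt$cv); ry <- midrank(unname(vols2))
  rho_o <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(out2$rho, rho_o, tolerance = 1e-12)

  # null: independent CV, n = 48, fixed seed
  set.seed(48)
  cvt3 <- data.frame(feature = "f", patient_id = paste0("P", 1:48),
                     cv = runif(48), excluded = FALSE)
  vols3 <- setNames(runif(48, 100, 5000), paste0("P", 1:48))
  expect_lt(abs(cv_size_correlation(cvt3, vols3)$rho), 0.4)

  # < 3 usable patients: skipped
  cvt4 <- data.frame(feature = "f", patient_id = paste0("P", 1:3),
                     cv = c(0.1, NA, 0.2), excluded = c(FALSE, TRUE, FALSE))
  out4 <- cv_size_correlation(cvt4, vols)
  expect_equal(nrow(out4), 0)
  expect_length(attr(out4, "skipped"), 1)
})
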