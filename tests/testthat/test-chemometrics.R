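# PLS1 regression, the RGB-statistics OLS baseline, and the fit metrics.

test_that("a noiseless two-latent-factor response is recovered exactly", {
  set.seed(31)
  scores <- matrix(rnorm(40 * 2), 40)
  loadings <- matrix(rnorm(360 * 2), 360)
  x <- scores %*% t(loadings)
  y <- as.numeric(scores %*% c(2, -1))
  fit <- fitPLSR(x, y, ncomp = 2, validation = "none")
  expect_equal(fitReport(fit)$r2_calibration, 1, tolerance = 1e-6)
})

test_that("permuted responses give near-zero validation R2", {
  ds <- syntheticRegressionSet(60, noiseSd = 0.01, seed = 32)
  # leave-one-out validation: every sample is predicted out-of-fit, so the
  # null distribution of R2 is tight around (or below) zero
  r2 <- vapply(1:20, function(k) {
    yp <- withr::with_seed(1000 + k, sample(ds$response))
    f <- fitPLSR(ds$predictors, yp, ncomp = 2, validation = "loo")
    fitReport(f)$r2_validation
  }, numeric(1))
  expect_true(all(r2 < 0.2))
  expect_lt(mean(r2), 0.05)
})

test_that("PLS1 at full predictor rank reproduces ordinary least squares", {
  set.seed(33)
  x <- matrix(rnorm(50 * 6), 50,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.numeric(x %*% rnorm(6) + rnorm(50, 0, 0.3))
  fp <- fitPLSR(x, y, ncomp = 6, seed = 5)
  fm <- fitMVR(x, y, seed = 5)
  expect_equal(fp@coefficients, fm@coefficients, tolerance = 1e-6)
  expect_equal(fp@intercept, fm@intercept, tolerance = 1e-6)
  for (f in c("r2_calibration", "r2_validation",
              "rmse_pct_calibration", "rmse_pct_validation"))
    expect_equal(fitReport(fp)[[f]], fitReport(fm)[[f]], tolerance = 1e-6)
})

test_that("PLS1 predictions match an independent PLS implementation", {
  set.seed(34)
  x <- matrix(rnorm(30 * 12), 30, dimnames = list(NULL, paste0("v", 1:12)))
  y <- as.numeric(x %*% rnorm(12) + rnorm(30, 0, 0.2))
  ours <- fitPLSR(x, y, ncomp = 4, validation = "none")
  ref <- mixOmics::pls(x, y, ncomp = 4, mode = "regression", scale = FALSE)
  refPred <- predict(ref, x)$predict[, , 4]
  expect_equal(predict(ours, x), as.numeric(refPred), tolerance = 1e-8)
})

test_that("RGB summary features are channel means and population SDs", {
  red <- uniformImage(c(255, 0, 0), 8, 8)
  expect_identical(unname(rgbSummaryFeatures(red)),
                   c(255, 0, 0, 0, 0, 0))
  halfrg <- uniformImage(c(255, 0, 0), 8, 8)
  halfrg[, 5:8, 1] <- 0; halfrg[, 5:8, 2] <- 255
  f <- rgbSummaryFeatures(halfrg)
  expect_identical(unname(f[c("mean_r", "mean_g")]), c(127.5, 127.5))
  # two-point population SD: |a - b| / 2
  expect_equal(unname(f[c("sd_r", "sd_g")]), c(127.5, 127.5))
  checker <- uniformImage(c(0, 0, 0), 2, 2)
  checker[1, 1, ] <- c(200, 40, 60); checker[2, 2, ] <- c(200, 40, 60)
  checker[1, 2, ] <- c(100, 80, 20); checker[2, 1, ] <- c(100, 80, 20)
  f <- rgbSummaryFeatures(checker)
  expect_equal(unname(f), c(150, 60, 40, 50, 20, 20))
})

test_that("the OLS baseline behaves on exact, null and singular designs", {
  set.seed(35)
  x <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("f", 1:6)))
  yExact <- as.numeric(x %*% c(1, -2, 0.5, 3, 0, 1) + 4)
  expect_equal(fitReport(fitMVR(x, yExact, seed = 1))$r2_calibration, 1,
               tolerance = 1e-9)
  yNull <- rnorm(40)
  rep <- fitReport(fitMVR(x, yNull, seed = 1))
  expect_lt(rep$r2_validation, 0.5)
  xs <- cbind(x, f7 = x[, 1] + x[, 2])  # exactly collinear column
  expect_error(fitMVR(xs, yExact, seed = 1), "f7")
})

test_that("RMSE% is the RMSE relative to the mean measured value", {
  expect_identical(rmsePercent(c(1, 2, 3), c(1, 2, 3)), 0)
  m <- c(8, 10, 12)
  expect_equal(rmsePercent(m + 0.7, m), 100 * 0.7 / 10)
  expect_equal(rmsePercent(11, 10), 10)
  expect_error(rmsePercent(c(1, -1), c(1, -1)), "zero")
  expect_error(rmsePercent(1:3, 1:2), "equal length")
})

test_that("metrics are invariant to sample order given paired split labels", {
  set.seed(36)
  ds <- syntheticRegressionSet(30, noiseSd = 0.05, seed = 36)
  cal <- sort(withr::with_seed(99, sample.int(30, 21)))
  f1 <- fitPLSR(ds$predictors, ds$response, ncomp = 5, calibration = cal)
  perm <- withr::with_seed(100, sample.int(30))
  calPerm <- which(perm %in% cal)
  f2 <- fitPLSR(ds$predictors[perm, ], ds$response[perm], ncomp = 5,
                calibration = calPerm)
  for (f in c("r2_calibration", "r2_validation",
              "rmse_pct_calibration", "rmse_pct_validation"))
    expect_equal(fitReport(f1)[[f]], fitReport(f2)[[f]], tolerance = 1e-8)
})

test_that("recovery degrades monotonically with response noise", {
  r2 <- vapply(c(0.01, 0.05, 0.1), function(s) {
    ds <- syntheticRegressionSet(60, noiseSd = s, seed = 11)
    fitReport(fitPLSR(ds$predictors, ds$response, seed = 11))$r2_validation
  }, numeric(1))
  expect_gt(r2[1], 0.9)
  expect_true(all(diff(r2) < 0))
})

test_that("invalid datasets and component counts are rejected", {
  x <- matrix(rnorm(20 * 5), 20, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(20)
  xb <- x; xb[3, 2] <- NA
  expect_error(fitPLSR(xb, y), "f2")
  expect_error(fitPLSR(x, y, ncomp = 25), "between 1 and")
  expect_error(fitPLSR(x[1:3, ], y[1:3]), "at least 4")
  expect_error(fitMVR(x[1:5, ], y[1:5]), "n > p")
  expect_error(fitPLSR(matrix(1, 20, 5), y, ncomp = 2), "degenerate")
})

test_that("leave-one-out validation fills the validation metrics", {
  set.seed(37)
  x <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.numeric(x %*% c(1, 2, -1, 0.5) + rnorm(20, 0, 0.1))
  f <- fitPLSR(x, y, ncomp = 4, validation = "loo")
  expect_gt(fitReport(f)$r2_validation, 0.9)
  expect_identical(f@split$type, "leave-one-out")
  fm <- fitMVR(x, y, validation = "loo")
  expect_gt(fitReport(fm)$r2_validation, 0.9)
})
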