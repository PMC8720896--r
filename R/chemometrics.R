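# Regressions from spectra (PLS1) and from RGB summary statistics (OLS
# baseline) to quality parameters, with R-squared and RMSE% reports.

.checkDataset <- function(x, y) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("predictors must be numeric")
  bad <- which(!apply(x, 2L, function(col) all(is.finite(col))))
  if (length(bad))
    stop("non-finite predictor columns: ",
         paste(if (is.null(colnames(x))) bad else colnames(x)[bad],
               collapse = ", "))
  if (anyNA(y) || any(!is.finite(y))) stop("response must be finite")
  if (nrow(x) != length(y)) stop("predictor rows and response length differ")
  if (nrow(x) < 4L) stop("at least 4 samples are required")
  x
}

# 70/30 random split (seeded) unless explicit calibration indices are given
.makeSplit <- function(n, validation, trainFraction, seed, calibration) {
  if (!is.null(calibration)) {
    cal <- sort(as.integer(calibration))
    if (any(cal < 1L) || any(cal > n)) stop("calibration indices out of range")
    return(list(type = "explicit", seed = NA_integer_, calibration = cal,
                validation = setdiff(seq_len(n), cal)))
  }
  switch(validation,
    none = list(type = "none", seed = NA_integer_,
                calibration = seq_len(n), validation = integer(0)),
    split = {
      nCal <- max(2L, round(trainFraction * n))
      cal <- sort(withr::with_seed(seed, sample.int(n, nCal)))
      list(type = sprintf("random %d/%d split", round(100 * trainFraction),
                          round(100 * (1 - trainFraction))),
           seed = as.integer(seed), calibration = cal,
           validation = setdiff(seq_len(n), cal))
    },
    loo = list(type = "leave-one-out", seed = NA_integer_,
               calibration = seq_len(n), validation = integer(0)))
}

# PLS1 by NIPALS with deflation, on mean-centered (optionally scaled) data.
# Returns coefficients on the original predictor scale.
.pls1 <- function(x, y, ncomp, scale = FALSE) {
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x); ym <- mean(y)
  sdev <- if (scale) apply(x, 2L, stats::sd) else rep(1, p)
  sdev[sdev == 0] <- 1
  X <- sweep(sweep(x, 2L, xm), 2L, sdev, "/")
  yd <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  Xd <- X
  a <- 0L
  tol <- 1e-12 * max(1, sum(X^2))
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw^2 <= tol) break       # residual response orthogonal to predictors
    w <- w / nw
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    if (t2 <= tol) break
    P[, k] <- crossprod(Xd, tt) / t2
    Q[k] <- sum(yd * tt) / t2
    W[, k] <- w
    Xd <- Xd - tt %*% t(P[, k])
    yd <- yd - tt * Q[k]
    a <- k
  }
  if (a == 0L)
    stop("degenerate predictors: no component could be extracted ",
         "(predictors carry no signal for the response)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[seq_len(a)]
  beta <- W %*% solve(crossprod(P, W), Q)
  beta <- as.numeric(beta) / sdev
  list(coef = beta, intercept = ym - sum(xm * beta), ncomp = a)
}

.plsPredict <- function(fit, x) as.numeric(x %*% fit$coef + fit$intercept)

.r2 <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

# leave-one-out RMSE per component count, used for automatic selection
.plsLooRMSE <- function(x, y, maxComp, scale) {
  n <- nrow(x)
  press <- matrix(NA_real_, n, maxComp)
  for (i in seq_len(n)) {
    f <- tryCatch(.pls1(x[-i, , drop = FALSE], y[-i], maxComp, scale),
                  error = function(e) NULL)
    if (is.null(f)) next
    # predictions at every component count up to the number extracted
    for (k in seq_len(f$ncomp)) {
      fk <- .pls1(x[-i, , drop = FALSE], y[-i], k, scale)
      press[i, k] <- (.plsPredict(fk, x[i, , drop = FALSE]) - y[i])^2
    }
  }
  sqrt(colMeans(press, na.rm = TRUE))
}

.buildReport <- function(method, coefs, intercept, ncomp, x, y, split) {
  cal <- split$calibration; val <- split$validation
  predAll <- as.numeric(x %*% coefs + intercept)
  r2c <- .r2(y[cal], predAll[cal])
  rmc <- rmsePercent(predAll[cal], y[cal])
  if (length(val)) {
    r2v <- .r2(y[val], predAll[val])
    rmv <- rmsePercent(predAll[val], y[val])
  } else {
    r2v <- NA_real_; rmv <- NA_real_
  }
  new("QualityFit", method = method,
      coefficients = coefs, intercept = intercept,
      nComponents = as.numeric(ncomp),
      r2Calibration = r2c, r2Validation = r2v,
      rmsePctCalibration = rmc, rmsePctValidation = rmv,
      split = split, fitted = predAll[cal])
}

#' Partial least squares regression of a quality parameter on spectra
#'
#' Fits a PLS1 latent-variable regression (NIPALS with deflation, on
#' mean-centered predictors) of a quality parameter — soluble solids,
#' firmness, etc. — on hue-spectrum bins or any other collinear predictor
#' block. Deterministic given the data, component count and split seed.
#'
#' @param x numeric predictor matrix, one row per sample (e.g. n x 360
#'   spectrum bins).
#' @param y numeric response with units (e.g. TSS in %).
#' @param ncomp number of latent components; `NULL` (default) selects the
#'   count minimizing leave-one-out RMSE on the calibration set, capped at 10.
#' @param validation `"split"` (default, random 70/30 by `seed`), `"loo"`
#'   (leave-one-out validation metrics) or `"none"`.
#' @param trainFraction calibration fraction for `validation = "split"`.
#' @param seed integer seed controlling the random split.
#' @param calibration optional explicit calibration row indices, overriding
#'   the random split (remaining rows become the validation set).
#' @param scale also divide predictors by their standard deviation
#'   (default FALSE: spectrum bins share units, so only centering is applied).
#' @return A [QualityFit-class]; see [fitReport()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 8), 40)
#' y <- x %*% rnorm(8)
#' fit <- fitPLSR(x, y, ncomp = 8)
#' fitReport(fit)$r2_calibration  # 1: noiseless linear response
#' @export
fitPLSR <- function(x, y, ncomp = NULL,
                    validation = c("split", "loo", "none"),
                    trainFraction = 0.7, seed = 1L, calibration = NULL,
                    scale = FALSE) {
  validation <- match.arg(validation)
  x <- .checkDataset(x, y)
  n <- nrow(x); p <- ncol(x)
  split <- .makeSplit(n, validation, trainFraction, seed, calibration)
  cal <- split$calibration
  xc <- x[cal, , drop = FALSE]; yc <- y[cal]
  maxComp <- min(length(cal) - 1L, p)
  if (!is.null(ncomp)) {
    ncomp <- as.integer(ncomp)
    if (ncomp < 1L || ncomp > maxComp)
      stop("'ncomp' must be between 1 and min(n_samples - 1, p) = ", maxComp)
  } else {
    nTry <- min(10L, maxComp - 1L, length(cal) - 2L)
    if (nTry < 1L) {
      ncomp <- 1L
    } else {
      rmse <- .plsLooRMSE(xc, yc, nTry, scale)
      ncomp <- which.min(rmse)
      if (!length(ncomp)) ncomp <- 1L
    }
  }
  fit <- .pls1(xc, yc, ncomp, scale)
  if (!is.null(colnames(x))) names(fit$coef) <- colnames(x)
  if (validation == "loo") {
    looPred <- vapply(seq_len(n), function(i) {
      f <- .pls1(x[-i, , drop = FALSE], y[-i], min(fit$ncomp, n - 2L), scale)
      .plsPredict(f, x[i, , drop = FALSE])
    }, numeric(1))
    out <- .buildReport("plsr", fit$coef, fit$intercept, fit$ncomp, x, y,
                        split)
    out@r2Validation <- .r2(y, looPred)
    out@rmsePctValidation <- rmsePercent(looPred, y)
    return(out)
  }
  .buildReport("plsr", fit$coef, fit$intercept, fit$ncomp, x, y, split)
}

#' RGB summary features of an image
#'
#' The six global color statistics a conventional multivariate-regression
#' baseline uses: mean and standard deviation of each RGB channel.
#' Standard deviations are population ones (divisor n), documented so the
#' feature is reproducible across implementations.
#'
#' @inheritParams rgbToChroma
#' @return Named numeric vector
#'   `(mean_r, mean_g, mean_b, sd_r, sd_g, sd_b)`.
#' @export
rgbSummaryFeatures <- function(image) {
  .checkRGBArray(image)
  ch <- lapply(1:3, function(k) as.numeric(image[, , k]))
  m <- vapply(ch, mean, numeric(1))
  s <- vapply(ch, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
  stats::setNames(c(m, s),
                  c("mean_r", "mean_g", "mean_b", "sd_r", "sd_g", "sd_b"))
}

#' Ordinary multivariate regression baseline
#'
#' Ordinary least squares (with intercept) of a quality parameter on a small
#' feature set, typically the six [rgbSummaryFeatures()]. Reports the same
#' metrics as [fitPLSR()] for side-by-side comparison.
#'
#' @inheritParams fitPLSR
#' @param x numeric feature matrix with few columns (n_samples > ncol(x)).
#' @return A [QualityFit-class].
#' @export
fitMVR <- function(x, y, validation = c("split", "loo", "none"),
                   trainFraction = 0.7, seed = 1L, calibration = NULL) {
  validation <- match.arg(validation)
  x <- .checkDataset(x, y)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("MVR needs more samples than features (n > p)")
  split <- .makeSplit(n, validation, trainFraction, seed, calibration)
  cal <- split$calibration
  if (length(cal) <= p) stop("calibration set too small for ", p, " features")
  df <- data.frame(y = y[cal], x[cal, , drop = FALSE])
  lmfit <- stats::lm(y ~ ., data = df)
  coefs <- stats::coef(lmfit)
  if (anyNA(coefs))
    stop("singular design matrix; aliased columns: ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "))
  out <- .buildReport("mvr", stats::setNames(coefs[-1L], colnames(x)),
                      unname(coefs[1L]), NA_real_, x, y, split)
  if (validation == "loo") {
    looPred <- vapply(seq_len(n), function(i) {
      dfi <- data.frame(y = y[-i], x[-i, , drop = FALSE])
      fi <- stats::lm(y ~ ., data = dfi)
      unname(stats::predict(fi, data.frame(x[i, , drop = FALSE])))
    }, numeric(1))
    out@r2Validation <- .r2(y, looPred)
    out@rmsePctValidation <- rmsePercent(looPred, y)
  }
  out
}

#' Root mean squared error as a percentage of the measured values
#'
#' `100 * RMSE(predicted, measured) / mean(measured)` — prediction error
#' relative to the magnitude of the measured quality parameter. The mean (not
#' per-sample division) is used as denominator so that measurements near zero
#' do not blow the statistic up.
#'
#' @param predicted,measured numeric vectors of equal length.
#' @return A single non-negative number (percent).
#' @examples
#' rmsePercent(11, 10)  # 10
#' @export
rmsePercent <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("'predicted' and 'measured' must have equal length")
  m <- mean(measured)
  if (abs(m) < .Machine$double.eps * 100)
    stop("mean of measured values is zero; RMSE% is undefined")
  100 * sqrt(mean((predicted - measured)^2)) / m
}

#' @rdname accessors
#' @export
setMethod("fitReport", "QualityFit", function(object) {
  list(method = object@method,
       n_components = object@nComponents,
       r2_calibration = object@r2Calibration,
       r2_validation = object@r2Validation,
       rmse_pct_calibration = object@rmsePctCalibration,
       rmse_pct_validation = object@rmsePctValidation,
       split = object@split[c("type", "seed")],
       n_calibration = length(object@split$calibration),
       n_validation = length(object@split$validation))
})

#' @describeIn fitPLSR predict responses for new predictor rows.
#' @param object a [QualityFit-class].
#' @param newdata numeric matrix with the same columns the model was fit on.
#' @param ... ignored.
#' @export
setMethod("predict", "QualityFit", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@coefficients))
    stop("newdata must have ", length(object@coefficients), " columns")
  as.numeric(newdata %*% object@coefficients + object@intercept)
})

setMethod("show", "QualityFit", function(object) {
  cat(sprintf("QualityFit [%s]%s\n", object@method,
              if (!is.na(object@nComponents))
                sprintf(", %d components", object@nComponents) else ""))
  cat(sprintf("  calibration: R2 = %.4f, RMSE%% = %.3f (n = %d)\n",
              object@r2Calibration, object@rmsePctCalibration,
              length(object@split$calibration)))
  if (length(object@split$validation))
    cat(sprintf("  validation:  R2 = %.4f, RMSE%% = %.3f (n = %d)\n",
                object@r2Validation, object@rmsePctValidation,
                length(object@split$validation)))
  cat("  split:", object@split$type, "\n")
})
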