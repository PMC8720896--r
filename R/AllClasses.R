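#' @import methods
NULL

#' HueSpectrum: a 360-bin saturation-weighted hue histogram
#'
#' A hue spectrum summarizes the color of an image as a vector indexed by
#' integer hue degree 1..360 (degree 0 is folded into 360, so bin 360 is red).
#' Each pixel whose normalized saturation exceeds a threshold contributes its
#' saturation — not a count — to the bin of its rounded hue angle, and the
#' vector is divided by the number of contributing pixels so that spectra of
#' images of different size are comparable. Neutral pixels (white, gray,
#' black) have saturation 0 and never contribute, which removes neutral
#' backgrounds without any segmentation step.
#'
#' @slot values numeric(360), non-negative bin values.
#' @slot nIncluded number of pixels above the saturation threshold (for an
#'   aggregate spectrum, the mean count over the averaged spectra).
#' @slot totalPixels number of pixels in the source image.
#' @slot threshold saturation threshold used, in \[0, 1).
#' @slot normalization `"included"` (divide by the above-threshold pixel
#'   count) or `"total"` (divide by all pixels).
#' @slot cropRange integer(0) for a full spectrum, or `c(lo, hi)` degrees if
#'   the spectrum was cropped (wrapped ranges with lo > hi permitted).
#' @slot aggregate TRUE if the object is an average of several spectra.
#'
#' @seealso [computeHueSpectrum()], [cropSpectrum()], [averageSpectra()],
#'   [findPeaks()], [pqsPoint()]
#' @export
setClass("HueSpectrum",
  representation(
    values = "numeric",
    nIncluded = "numeric",
    totalPixels = "numeric",
    threshold = "numeric",
    normalization = "character",
    cropRange = "integer",
    aggregate = "logical"
  ),
  prototype(
    values = numeric(360), nIncluded = 0, totalPixels = 0,
    threshold = 0.05, normalization = "included",
    cropRange = integer(0), aggregate = FALSE
  )
)

setValidity("HueSpectrum", function(object) {
  msg <- character(0)
  if (length(object@values) != 360L)
    msg <- c(msg, "'values' must have length 360 (one bin per hue degree)")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "'values' must be non-negative")
  if (length(object@threshold) != 1L || object@threshold < 0 ||
      object@threshold >= 1)
    msg <- c(msg, "'threshold' must be a single value in [0, 1)")
  if (!object@normalization %in% c("included", "total"))
    msg <- c(msg, "'normalization' must be \"included\" or \"total\"")
  if (!length(object@cropRange) %in% c(0L, 2L))
    msg <- c(msg, "'cropRange' must be empty or c(lo, hi)")
  if (length(object@cropRange) == 2L &&
      (any(object@cropRange < 1L) || any(object@cropRange > 360L)))
    msg <- c(msg, "'cropRange' degrees must lie in 1..360")
  if (length(msg)) msg else TRUE
})

#' Construct a HueSpectrum
#'
#' Low-level constructor; most users obtain spectra from
#' [computeHueSpectrum()].
#'
#' @param values numeric(360) bin values.
#' @param nIncluded count of pixels above threshold.
#' @param totalPixels count of all pixels in the source image.
#' @param threshold saturation threshold in \[0, 1).
#' @param normalization `"included"` or `"total"`.
#' @param cropRange integer(0) or c(lo, hi).
#' @param aggregate logical, TRUE for averaged spectra.
#' @return A [HueSpectrum-class] object.
#' @export
HueSpectrum <- function(values, nIncluded = 0, totalPixels = 0,
                        threshold = 0.05, normalization = "included",
                        cropRange = integer(0), aggregate = FALSE) {
  new("HueSpectrum",
    values = as.numeric(values), nIncluded = as.numeric(nIncluded),
    totalPixels = as.numeric(totalPixels), threshold = as.numeric(threshold),
    normalization = normalization, cropRange = as.integer(cropRange),
    aggregate = isTRUE(aggregate))
}

#' PQSPoint: the gravity point of a spectrum's polar figure
#'
#' The Polar Qualification System (PQS) compresses a spectrum into a single
#' 2-D point: the spectrum is drawn as a polar figure (radius = bin value,
#' angle = hue degree) and the centroid of that figure, computed by
#' triangular decomposition, is the PQS point.
#'
#' @slot x,y gravity point coordinates.
#' @slot area total area of the polar figure (sum of signed triangle areas).
#' @slot binAngle angular step between consecutive bins, radians (2*pi/360).
#' @slot range the degree range `c(lo, hi)` the summation covered.
#' @seealso [pqsPoint()], [pqsPointInRange()]
#' @export
setClass("PQSPoint",
  representation(x = "numeric", y = "numeric", area = "numeric",
                 binAngle = "numeric", range = "integer"))

setValidity("PQSPoint", function(object) {
  if (length(object@x) != 1L || length(object@y) != 1L)
    return("'x' and 'y' must be single values")
  if (object@area < 0) return("'area' must be non-negative")
  TRUE
})

#' QualityFit: a fitted quality-prediction regression with its report
#'
#' Holds either a PLS1 latent-variable regression on spectrum bins or an
#' ordinary least-squares model on RGB summary statistics, together with
#' calibration/validation metrics (R-squared and RMSE%) and the split that
#' produced them.
#'
#' @slot method `"plsr"` or `"mvr"`.
#' @slot coefficients named regression coefficients on the original
#'   predictor scale.
#' @slot intercept model intercept.
#' @slot nComponents number of latent components (NA for mvr).
#' @slot r2Calibration,r2Validation coefficient of determination
#'   (1 - SSres/SStot); validation slot is NA when no held-out set exists.
#' @slot rmsePctCalibration,rmsePctValidation root mean squared error as a
#'   percentage of the mean measured value.
#' @slot split list describing the validation scheme (type, seed,
#'   calibration / validation indices).
#' @slot fitted fitted values on the calibration set.
#' @seealso [fitPLSR()], [fitMVR()], [fitReport()]
#' @export
setClass("QualityFit",
  representation(
    method = "character", coefficients = "numeric", intercept = "numeric",
    nComponents = "numeric", r2Calibration = "numeric",
    r2Validation = "numeric", rmsePctCalibration = "numeric",
    rmsePctValidation = "numeric", split = "list", fitted = "numeric"))
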