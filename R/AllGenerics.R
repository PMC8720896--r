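#' Compute the hue spectrum of an RGB image
#'
#' Transforms every pixel to the chromatic plane, keeps pixels whose
#' normalized saturation exceeds `threshold`, rounds their hue to the nearest
#' integer degree (0 folded into 360), sums the saturations per degree bin and
#' divides by the number of contributing pixels. With zero or one
#' contributing pixel the spectrum is all-zero (not an error).
#'
#' @param x an RGB image: an H x W x 3 numeric array with channel values in
#'   \[0, 255\] (channel order R, G, B), or a path to a PNG/JPEG/TIFF file.
#' @param threshold saturation threshold in \[0, 1); a pixel contributes only
#'   if its saturation is strictly greater. Default 0.05, which removes
#'   near-neutral backgrounds.
#' @param normalization `"included"` (default) divides bin sums by the number
#'   of above-threshold pixels; `"total"` divides by all pixels of the image.
#' @param ... passed between methods.
#' @return A [HueSpectrum-class].
#' @examples
#' img <- array(0, c(4, 4, 3)); img[, , 1] <- 255  # uniform pure red
#' sp <- computeHueSpectrum(img)
#' spectrumValues(sp)[360]  # 1: all saturation mass at red
#' @export
setGeneric("computeHueSpectrum",
  function(x, threshold = 0.05, normalization = c("included", "total"), ...)
    standardGeneric("computeHueSpectrum"))

#' Gravity point of a spectrum's polar figure (PQS)
#'
#' Places the 360 bin values at polar coordinates (radius = value, angle =
#' degree), decomposes the resulting closed figure into triangles anchored at
#' the origin, and returns the area-weighted centroid. A constant spectrum
#' maps to the origin by symmetry; a spectrum without two consecutive
#' non-zero bins has zero area and raises an error of class
#' `huespectra_undefined_pqs`.
#'
#' @param spectrum a [HueSpectrum-class] or a numeric vector of 360 bin
#'   values.
#' @param ... passed between methods.
#' @return A [PQSPoint-class].
#' @export
setGeneric("pqsPoint", function(spectrum, ...) standardGeneric("pqsPoint"))

#' @rdname pqsPoint
#' @param lo,hi degree range (1..360); `lo > hi` wraps through 360/1. The
#'   summation is restricted to consecutive bin pairs inside the range (an
#'   open fan, no closure through the excluded arc); the angular step stays
#'   at 1 degree.
#' @export
setGeneric("pqsPointInRange", function(spectrum, lo, hi, ...)
  standardGeneric("pqsPointInRange"))

#' Locate peaks of a hue spectrum
#'
#' Finds circular local maxima (bin 360 is adjacent to bin 1) above a height
#' cutoff and measures each peak's full width at half maximum by linear
#' interpolation on both flanks, with the flank search also circular.
#' Plateau maxima are reported once, at the lowest degree of the plateau.
#'
#' @param spectrum a [HueSpectrum-class] or numeric vector of 360 values.
#' @param minHeight minimum peak height; peaks at or below it are dropped.
#' @param ... passed between methods.
#' @return A data.frame with columns `location` (degree), `height`, `width`
#'   (degrees, FWHM); zero rows when no peak qualifies.
#' @export
setGeneric("findPeaks", function(spectrum, minHeight = 0, ...)
  standardGeneric("findPeaks"))

#' @rdname accessors
#' @export
setGeneric("spectrumValues", function(object) standardGeneric("spectrumValues"))
#' @rdname accessors
#' @export
setGeneric("nIncluded", function(object) standardGeneric("nIncluded"))
#' @rdname accessors
#' @export
setGeneric("totalPixels", function(object) standardGeneric("totalPixels"))
#' @rdname accessors
#' @export
setGeneric("spectrumThreshold", function(object)
  standardGeneric("spectrumThreshold"))
#' @rdname accessors
#' @export
setGeneric("normalizationMode", function(object)
  standardGeneric("normalizationMode"))
#' @rdname accessors
#' @export
setGeneric("cropRange", function(object) standardGeneric("cropRange"))
#' @rdname accessors
#' @export
setGeneric("pqsX", function(object) standardGeneric("pqsX"))
#' @rdname accessors
#' @export
setGeneric("pqsY", function(object) standardGeneric("pqsY"))
#' @rdname accessors
#' @export
setGeneric("pqsArea", function(object) standardGeneric("pqsArea"))
#' @rdname accessors
#' @export
setGeneric("fitReport", function(object) standardGeneric("fitReport"))
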