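# The 360-bin saturation-weighted hue histogram, plus averaging, cropping
# and peak characterization.

# Integer conversion rounds half away from zero (hue >= 0, so floor(x + 0.5)
# is equivalent). R's round() is banker's rounding, which would disagree at
# exact .5 hues.
.roundHalfUp <- function(x) floor(x + 0.5)

# ordered degree sequence of a (possibly wrapped) range
.rangeDegrees <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (anyNA(c(lo, hi)) || lo < 1L || lo > 360L || hi < 1L || hi > 360L)
    stop("range degrees must lie in 1..360")
  if (lo <= hi) lo:hi else c(lo:360L, 1:hi)
}

#' @rdname computeHueSpectrum
#' @export
setMethod("computeHueSpectrum", "array",
  function(x, threshold = 0.05, normalization = c("included", "total"), ...) {
    normalization <- match.arg(normalization)
    if (length(threshold) != 1L || is.na(threshold) ||
        threshold < 0 || threshold >= 1)
      stop("'threshold' must be a single value in [0, 1)")
    .checkRGBArray(x)
    hs <- rgbToHueSat(x)
    keep <- hs$saturation > threshold      # strict, so tv = 0 still drops grays
    fs <- hs$saturation[keep]
    fc <- .roundHalfUp(hs$hue[keep])
    fc[fc == 0] <- 360                     # degree 0 folds into bin 360 (red)
    n <- length(fc)
    total <- prod(dim(x)[1:2])
    vals <- numeric(360)
    if (n > 1L) {
      sums <- rowsum(fs, fc)
      vals[as.integer(rownames(sums))] <- sums
      vals <- vals / if (normalization == "included") n else total
    }
    HueSpectrum(vals, nIncluded = n, totalPixels = total,
                threshold = threshold, normalization = normalization)
  })

#' @rdname computeHueSpectrum
#' @export
setMethod("computeHueSpectrum", "character",
  function(x, threshold = 0.05, normalization = c("included", "total"), ...) {
    computeHueSpectrum(readRGBImage(x), threshold = threshold,
                       normalization = normalization, ...)
  })

#' Average several hue spectra
#'
#' Element-wise arithmetic mean of spectra computed with the same threshold
#' and normalization mode, e.g. to summarize all fruit of one sampling day.
#' The result is flagged as an aggregate and carries the mean included-pixel
#' count.
#'
#' @param spectra non-empty list of [HueSpectrum-class] objects sharing
#'   threshold and normalization.
#' @return A [HueSpectrum-class] with `aggregate = TRUE`.
#' @export
averageSpectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0L)
    stop("'spectra' must be a non-empty list of HueSpectrum objects")
  if (!all(vapply(spectra, is, logical(1), "HueSpectrum")))
    stop("'spectra' must contain only HueSpectrum objects")
  thr <- vapply(spectra, spectrumThreshold, numeric(1))
  if (length(unique(thr)) != 1L)
    stop("cannot average spectra computed with different thresholds: ",
         paste(unique(thr), collapse = ", "))
  nm <- vapply(spectra, normalizationMode, character(1))
  if (length(unique(nm)) != 1L)
    stop("cannot average spectra with different normalization modes")
  vals <- rowMeans(vapply(spectra, spectrumValues, numeric(360)))
  HueSpectrum(vals,
    nIncluded = mean(vapply(spectra, nIncluded, numeric(1))),
    totalPixels = mean(vapply(spectra, totalPixels, numeric(1))),
    threshold = thr[1L], normalization = nm[1L], aggregate = TRUE)
}

#' Restrict a spectrum to a hue range
#'
#' Zeroes every bin outside `[lo, hi]` degrees, keeping the originals inside.
#' Wrapped ranges (`lo > hi`) pass through 360/1, which matters because red
#' straddles that boundary. Used to focus analysis on the color range a
#' produce actually traverses (e.g. green to red during ripening).
#'
#' @param spectrum a [HueSpectrum-class].
#' @param lo,hi degree bounds in 1..360.
#' @return A [HueSpectrum-class] with `cropRange(spectrum) == c(lo, hi)`.
#' @export
cropSpectrum <- function(spectrum, lo, hi) {
  stopifnot(is(spectrum, "HueSpectrum"))
  degs <- .rangeDegrees(lo, hi)
  vals <- numeric(360)
  vals[degs] <- spectrum@values[degs]
  initialize(spectrum, values = vals,
             cropRange = c(as.integer(lo), as.integer(hi)))
}

# circular FWHM half-width on one flank; direction -1 = left, +1 = right
.halfWidth <- function(v, loc, half, direction) {
  prev <- v[loc]
  for (d in 1:359) {
    idx <- ((loc - 1 + direction * d) %% 360) + 1
    cur <- v[idx]
    if (cur < half)
      return((d - 1) + (prev - half) / (prev - cur))
    prev <- cur
  }
  180  # level never crossed on this flank; cap at half the circle
}

#' @rdname findPeaks
#' @export
setMethod("findPeaks", "numeric", function(spectrum, minHeight = 0, ...) {
  v <- spectrum
  if (length(v) != 360L) stop("spectrum vector must have length 360")
  if (minHeight < 0) stop("'minHeight' must be >= 0")
  empty <- data.frame(location = integer(0), height = numeric(0),
                      width = numeric(0))
  if (all(v == v[1L])) return(empty)  # constant: no local maximum exists
  # runs of equal values, treated circularly: rotate so a run boundary is at 1
  start <- which(v != c(v[360L], v[-360L]))[1L]
  rot <- ((start - 1L + seq_len(360L) - 1L) %% 360L) + 1L  # degrees, rotated order
  r <- rle(v[rot])
  ends <- cumsum(r$lengths)
  begins <- c(1L, ends[-length(ends)] + 1L)
  k <- length(r$values)
  peaks <- list()
  for (i in seq_len(k)) {
    prev <- r$values[if (i == 1L) k else i - 1L]
    nxt <- r$values[if (i == k) 1L else i + 1L]
    h <- r$values[i]
    if (h > prev && h > nxt && h > minHeight) {
      run <- rot[begins[i]:ends[i]]           # degrees forming the plateau
      loc <- min(run)                          # tie-break: lowest degree
      # unless the plateau itself wraps 360 -> 1, where "lowest" means the
      # first degree of the plateau along the circle
      if (length(run) > 1L && any(diff(run) != 1L)) loc <- run[1L]
      w <- .halfWidth(v, loc, h / 2, -1L) + .halfWidth(v, loc, h / 2, +1L)
      peaks[[length(peaks) + 1L]] <-
        data.frame(location = loc, height = h, width = w)
    }
  }
  if (length(peaks) == 0L) return(empty)
  out <- do.call(rbind, peaks)
  out[order(out$location), , drop = FALSE]
})

#' @rdname findPeaks
#' @export
setMethod("findPeaks", "HueSpectrum", function(spectrum, minHeight = 0, ...) {
  findPeaks(spectrum@values, minHeight = minHeight, ...)
})

#' @rdname accessors
#' @name accessors
#' @title Accessors for HueSpectrum, PQSPoint and QualityFit objects
#' @param object the object to access.
#' @export
setMethod("spectrumValues", "HueSpectrum", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("nIncluded", "HueSpectrum", function(object) object@nIncluded)
#' @rdname accessors
#' @export
setMethod("totalPixels", "HueSpectrum", function(object) object@totalPixels)
#' @rdname accessors
#' @export
setMethod("spectrumThreshold", "HueSpectrum",
          function(object) object@threshold)
#' @rdname accessors
#' @export
setMethod("normalizationMode", "HueSpectrum",
          function(object) object@normalization)
#' @rdname accessors
#' @export
setMethod("cropRange", "HueSpectrum", function(object) object@cropRange)

setMethod("show", "HueSpectrum", function(object) {
  nz <- sum(object@values > 0)
  cat("HueSpectrum (360 bins,", nz, "non-zero)\n")
  cat("  threshold:", object@threshold,
      " normalization:", object@normalization, "\n")
  cat("  pixels included:", object@nIncluded, "of", object@totalPixels, "\n")
  if (length(object@cropRange))
    cat("  cropped to: [", object@cropRange[1L], ",",
        object@cropRange[2L], "] degrees\n")
  if (object@aggregate) cat("  aggregate of several spectra\n")
  if (nz > 0) {
    pk <- findPeaks(object)
    if (nrow(pk))
      cat("  top peak:", pk$location[which.max(pk$height)], "deg, height",
          signif(max(pk$height), 4), "\n")
  }
})
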