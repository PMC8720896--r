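# Polar Qualification System: compress a spectrum into the gravity point of
# its polar figure by triangular decomposition. Each consecutive bin pair
# (V_i at angle i*alpha, V_{i+1} at angle (i+1)*alpha) spans, with the
# origin, a triangle of area V_i*V_{i+1}*sin(alpha)/2 whose centroid is
# (P_i + P_{i+1})/3; the PQS point is the area-weighted mean of these
# centroids. Zero-radius vertices contribute zero-area triangles naturally.

.undefinedPQSError <- function() {
  stop(errorCondition(
    paste("undefined PQS point: the polar figure has zero area",
          "(no two consecutive non-zero bins in the requested range)"),
    class = c("huespectra_undefined_pqs", "error", "condition")))
}

# degs: ordered degree sequence; closed: append the first pair to close the
# polygon (used for the full hue circle, which is a closed figure)
.pqsCore <- function(v, degs, closed) {
  alpha <- 2 * pi / 360
  i1 <- degs
  i2 <- if (closed) c(degs[-1L], degs[1L]) else degs[-1L]
  if (!closed) i1 <- degs[-length(degs)]
  r1 <- v[i1]; r2 <- v[i2]
  a1 <- i1 * alpha; a2 <- i2 * alpha
  tri <- r1 * r2 * sin(alpha)          # 2 * signed triangle area
  area <- sum(tri) / 2
  if (area <= 0) .undefinedPQSError()
  px <- sum((r1 * cos(a1) + r2 * cos(a2)) * tri) / (6 * area)
  py <- sum((r1 * sin(a1) + r2 * sin(a2)) * tri) / (6 * area)
  list(x = px, y = py, area = area, binAngle = alpha)
}

#' @rdname pqsPoint
#' @export
setMethod("pqsPoint", "numeric", function(spectrum, ...) {
  if (length(spectrum) != 360L) stop("spectrum vector must have length 360")
  res <- .pqsCore(spectrum, 1:360, closed = TRUE)
  new("PQSPoint", x = res$x, y = res$y, area = res$area,
      binAngle = res$binAngle, range = c(1L, 360L))
})

#' @rdname pqsPoint
#' @export
setMethod("pqsPoint", "HueSpectrum", function(spectrum, ...) {
  pqsPoint(spectrum@values, ...)
})

#' @rdname pqsPoint
#' @export
setMethod("pqsPointInRange", "numeric", function(spectrum, lo, hi, ...) {
  if (length(spectrum) != 360L) stop("spectrum vector must have length 360")
  degs <- .rangeDegrees(lo, hi)
  if (length(degs) < 2L)
    .undefinedPQSError()
  closed <- length(degs) == 360L   # full circle: close the polygon
  res <- .pqsCore(spectrum, degs, closed = closed)
  new("PQSPoint", x = res$x, y = res$y, area = res$area,
      binAngle = res$binAngle, range = c(as.integer(lo), as.integer(hi)))
})

#' @rdname pqsPoint
#' @export
setMethod("pqsPointInRange", "HueSpectrum", function(spectrum, lo, hi, ...) {
  pqsPointInRange(spectrum@values, lo, hi, ...)
})

#' @rdname accessors
#' @export
setMethod("pqsX", "PQSPoint", function(object) object@x)
#' @rdname accessors
#' @export
setMethod("pqsY", "PQSPoint", function(object) object@y)
#' @rdname accessors
#' @export
setMethod("pqsArea", "PQSPoint", function(object) object@area)

setMethod("show", "PQSPoint", function(object) {
  cat(sprintf("PQSPoint (%.6g, %.6g), area %.6g, range [%d, %d]\n",
              object@x, object@y, object@area,
              object@range[1L], object@range[2L]))
})
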