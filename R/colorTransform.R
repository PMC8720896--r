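# Chromatic-plane projection of RGB and the hue/saturation derived from it.
# The RGB cube projects onto a hexagon of circumradius 255; the neutral axis
# (R=G=B) collapses to the origin, so grays of any lightness have chroma 0.

.nonColorError <- function(what = "input") {
  stop(errorCondition(
    sprintf("non-color image: %s does not have exactly 3 channels (R, G, B)",
            what),
    class = c("huespectra_noncolor_image", "error", "condition")))
}

.checkRGBArray <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L)
    .nonColorError()
  if (dim(image)[3L] != 3L)
    .nonColorError()
  if (!is.numeric(image) || anyNA(image))
    stop("RGB image must be numeric without missing values")
  rng <- range(image)
  if (rng[1L] < 0 || rng[2L] > 255)
    stop("RGB channel values must lie in [0, 255]; ",
         "16-bit images must be rescaled explicitly before use")
  invisible(image)
}

#' Project RGB pixels onto the chromatic plane
#'
#' Each pixel (R, G, B) maps to `x = R - (G + B)/2`, `y = sqrt(3)/2 * (G - B)`
#' in double precision. The projection discards lightness: adding the same
#' constant to all three channels leaves (x, y) unchanged, which is why the
#' downstream hue spectrum ignores neutral backgrounds of any brightness.
#'
#' @param image an H x W x 3 numeric array, channel values in \[0, 255\].
#' @return A list with numeric H x W matrices `x` and `y`.
#' @examples
#' px <- array(c(0, 255, 0), c(1, 1, 3))  # pure green
#' rgbToChroma(px)  # x = -127.5, y = 255*sqrt(3)/2
#' @export
rgbToChroma <- function(image) {
  .checkRGBArray(image)
  hw <- dim(image)[1:2]
  r <- array(as.numeric(image[, , 1L]), hw)
  g <- array(as.numeric(image[, , 2L]), hw)
  b <- array(as.numeric(image[, , 3L]), hw)
  list(x = r - g / 2 - b / 2, y = (g - b) * sqrt(3) / 2)
}

#' Hue angle of chromatic-plane points
#'
#' Two-argument arctangent in degrees, with negative angles corrected by
#' +360 so the result lies in \[0, 360). The origin (neutral colors) is well
#' defined and returns 0; such pixels have saturation 0 and are excluded
#' downstream anyway.
#'
#' @param x,y chromatic-plane coordinates (any numeric shape; recycled
#'   together).
#' @return Hue in degrees, in \[0, 360), same shape as the inputs.
#' @export
chromaToHue <- function(x, y) {
  h <- atan2(y, x) * 180 / pi
  neg <- h < 0
  h[neg] <- h[neg] + 360
  # atan2(-eps, x>0) + 360 can round to exactly 360; keep the range half-open
  h[h >= 360] <- 0
  h
}

#' Saturation (normalized chroma) of chromatic-plane points
#'
#' Euclidean distance from the neutral axis divided by 255, so pure
#' primaries and secondaries reach 1 and grays are exactly 0.
#'
#' @inheritParams chromaToHue
#' @return Saturation in \[0, 1\], same shape as the inputs.
#' @export
chromaToSaturation <- function(x, y) {
  sqrt(x^2 + y^2) / 255
}

#' Per-pixel hue and saturation of an RGB image
#'
#' Single pass composing [rgbToChroma()], [chromaToHue()] and
#' [chromaToSaturation()].
#'
#' @inheritParams rgbToChroma
#' @return A list with H x W matrices `hue` (degrees, \[0, 360)) and
#'   `saturation` (\[0, 1\]).
#' @export
rgbToHueSat <- function(image) {
  ch <- rgbToChroma(image)
  list(hue = chromaToHue(ch$x, ch$y),
       saturation = chromaToSaturation(ch$x, ch$y))
}

#' RGB color realizing a given hue and saturation
#'
#' Inverts the chromatic projection: returns an (R, G, B) triple whose hue
#' angle and normalized saturation equal the request, choosing the lightness
#' as the midpoint of the feasible interval. Used by the synthetic-scene
#' generator; note that rounding the result to 8-bit integers perturbs the
#' realized hue slightly, so ground truth should be recomputed from the
#' rounded color.
#'
#' @param hue hue angle in degrees.
#' @param saturation normalized saturation in \[0, 1\]; must be reachable
#'   inside the RGB cube for the given hue.
#' @return Numeric length-3 vector (R, G, B) in \[0, 255\], unrounded.
#' @export
hueSatToRGB <- function(hue, saturation) {
  stopifnot(length(hue) == 1L, length(saturation) == 1L,
            saturation >= 0, saturation <= 1)
  a <- hue * pi / 180
  dx <- 255 * saturation * cos(a)
  dy <- 255 * saturation * sin(a)
  # channel offsets around the common lightness m (they sum to zero)
  off <- c(2 * dx / 3, -dx / 3 + dy / sqrt(3), -dx / 3 - dy / sqrt(3))
  loM <- max(-off)
  hiM <- min(255 - off)
  if (loM > hiM + 1e-9)
    stop("requested saturation ", saturation,
         " is not reachable at hue ", hue, " inside the RGB cube")
  m <- (loM + min(hiM, 255)) / 2
  pmin(pmax(m + off, 0), 255)
}
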