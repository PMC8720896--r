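# Deterministic synthetic scenes with known ground truth: colored shapes on
# neutral backgrounds, ripening series with a drifting hue peak, and a
# regression set pairing spectra with a quality-like response.

#' Describe a synthetic scene
#'
#' A scene is a neutral-gray canvas with colored shapes drawn on it in list
#' order (later objects overwrite earlier ones where they overlap), plus
#' optional i.i.d. Gaussian channel noise, clipped to \[0, 255\]. Shapes are
#' rasterized without anti-aliasing so pixel counts per color are exact
#' integers. This emulates produce photographed on a white/gray/black
#' background; it is not a camera model (no optics, illumination or sensor
#' noise structure).
#'
#' @param width,height canvas size in pixels.
#' @param background neutral background gray level in 0..255.
#' @param objects list of shapes from [sceneDisk()] / [sceneRect()].
#' @param noiseSd per-channel Gaussian noise standard deviation (intensity
#'   units), 0 for a noiseless scene.
#' @param seed integer seed making the noise reproducible.
#' @return A validated `SceneSpec` list.
#' @export
sceneSpec <- function(width = 64L, height = 64L, background = 255,
                      objects = list(), noiseSd = 0, seed = 1L) {
  stopifnot(width >= 1, height >= 1, background >= 0, background <= 255,
            noiseSd >= 0)
  for (ob in objects) {
    if (!is.list(ob) || is.null(ob$shape))
      stop("objects must come from sceneDisk() or sceneRect()")
    if (length(ob$color) != 3L || any(ob$color < 0) || any(ob$color > 255))
      stop("object colors must be RGB triples in [0, 255]")
    inside <- switch(ob$shape,
      disk = ob$cx - ob$r >= 1 && ob$cx + ob$r <= width &&
             ob$cy - ob$r >= 1 && ob$cy + ob$r <= height,
      rect = ob$x0 >= 1 && ob$x1 <= width && ob$y0 >= 1 && ob$y1 <= height &&
             ob$x0 <= ob$x1 && ob$y0 <= ob$y1,
      FALSE)
    if (!inside) stop("object extends outside the canvas")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background, objects = objects,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "SceneSpec")
}

#' @rdname sceneSpec
#' @param cx,cy center (pixel coordinates, 1-based: column, row).
#' @param r disk radius in pixels (pixel centers within r are filled).
#' @param color RGB triple in \[0, 255\].
#' @export
sceneDisk <- function(cx, cy, r, color)
  list(shape = "disk", cx = cx, cy = cy, r = r, color = as.numeric(color))

#' @rdname sceneSpec
#' @param x0,y0,x1,y1 inclusive rectangle corners (column, row).
#' @export
sceneRect <- function(x0, y0, x1, y1, color)
  list(shape = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
       color = as.numeric(color))

.objectMask <- function(ob, width, height) {
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rows <- matrix(seq_len(height), height, width)
  switch(ob$shape,
    disk = (cols - ob$cx)^2 + (rows - ob$cy)^2 <= ob$r^2,
    rect = cols >= ob$x0 & cols <= ob$x1 & rows >= ob$y0 & rows <= ob$y1,
    stop("unknown shape: ", ob$shape))
}

#' Render a synthetic scene to an RGB image
#'
#' @param spec a [sceneSpec()].
#' @return H x W x 3 numeric array of integer intensities in \[0, 255\].
#'   Identical spec and seed give bit-identical output.
#' @export
renderScene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  h <- spec$height; w <- spec$width
  img <- array(spec$background, c(h, w, 3L))
  for (ob in spec$objects) {
    m <- .objectMask(ob, w, h)
    for (k in 1:3) {
      plane <- img[, , k]
      plane[m] <- ob$color[k]
      img[, , k] <- plane
    }
  }
  if (spec$noiseSd > 0) {
    noise <- withr::with_seed(spec$seed,
      array(stats::rnorm(length(img), 0, spec$noiseSd), dim(img)))
    img <- pmin(pmax(img + noise, 0), 255)
  }
  round(img)
}

# disk with a narrow flat-hue core around the center column and a linear
# hue gradient toward the left/right edges. The core holds one exact color,
# so the dominant spectral bin stays pinned to the center hue even after
# 8-bit rounding scatters the flank hues; the flanks carry most of the mass
# and give the spectral bump smooth overlapping shoulders.
.gradientDiskImage <- function(size, radius, hueCenter, saturation,
                               hueSpread, background = 255,
                               noiseSd = 0, seed = 1L) {
  h <- w <- as.integer(size)
  cx <- cy <- (w + 1) / 2
  img <- array(background, c(h, w, 3L))
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rows <- matrix(seq_len(h), h, w)
  inDisk <- (cols - cx)^2 + (rows - cy)^2 <= radius^2
  core <- radius / 8
  for (x in seq_len(w)) {
    colMask <- inDisk[, x]
    if (!any(colMask)) next
    off <- x - cx
    hueX <- if (abs(off) <= core) hueCenter
            else hueCenter + hueSpread * (off - sign(off) * core) /
                   (2 * (radius - core))
    rgb <- round(hueSatToRGB(hueX %% 360, saturation))
    for (k in 1:3) img[colMask, x, k] <- rgb[k]
  }
  if (noiseSd > 0) {
    noise <- withr::with_seed(as.integer(seed),
      array(stats::rnorm(length(img), 0, noiseSd), dim(img)))
    img <- pmin(pmax(img + noise, 0), 255)
  }
  round(img)
}

#' Simulate a ripening series of disk images
#'
#' Produces `nSteps` images of a disk whose dominant hue interpolates
#' linearly from `hueStart` (green, 120) to `hueEnd` (red, 0) while its
#' saturation interpolates from `satStart` to `satEnd`, emulating the
#' green-to-red peak displacement seen when fruit ripen. A mild linear hue
#' gradient across the disk (`hueSpread` degrees over the diameter) gives
#' each spectrum a smooth unimodal bump instead of a one-bin spike, as real
#' fruit with color gradients do.
#'
#' @param nSteps number of images in the series.
#' @param hueStart,hueEnd dominant hue at the first / last step, degrees in
#'   \[0, 360).
#' @param satStart,satEnd saturation at the first / last step, in (0, 1\].
#' @param size canvas side (square), pixels.
#' @param radius disk radius, pixels.
#' @param hueSpread total hue variation across the disk diameter, degrees.
#' @param noiseSd per-channel Gaussian noise SD, 0 for noiseless.
#' @param seed integer seed (noise only; geometry is deterministic).
#' @return List of length `nSteps`; each element has `image`, `step`,
#'   `ripeness` (0 at start, 1 at end), and the ground-truth `hue`,
#'   `saturation` and `hueBin` (dominant-hue bin after 8-bit rounding of the
#'   disk's center-column color).
#' @export
ripeningSeries <- function(nSteps, hueStart = 120, hueEnd = 0,
                           satStart = 0.6, satEnd = 0.9,
                           size = 64L, radius = 24, hueSpread = 20,
                           noiseSd = 0, seed = 1L) {
  stopifnot(nSteps >= 1, hueStart >= 0, hueStart < 360,
            hueEnd >= 0, hueEnd < 360,
            satStart > 0, satStart <= 1, satEnd > 0, satEnd <= 1)
  lapply(seq_len(nSteps), function(i) {
    u <- if (nSteps == 1L) 0 else (i - 1) / (nSteps - 1)
    hue <- hueStart + u * (hueEnd - hueStart)
    sat <- satStart + u * (satEnd - satStart)
    img <- .gradientDiskImage(size, radius, hue, sat,
                              hueSpread = hueSpread, noiseSd = noiseSd,
                              seed = seed + i)
    # dominant bin realized after 8-bit rounding of the center-column color
    center <- round(hueSatToRGB(hue %% 360, sat))
    hs <- rgbToHueSat(array(center, c(1, 1, 3)))
    bin <- .roundHalfUp(hs$hue[1])
    if (bin == 0) bin <- 360
    list(image = img, step = i, ripeness = u, hue = hue %% 360,
         saturation = sat, hueBin = as.integer(bin))
  })
}

#' Synthetic spectra-vs-quality regression dataset
#'
#' Generates a ripening series, computes each image's hue spectrum, and
#' pairs it with a quality-like response that is affine in the ripeness
#' index plus Gaussian noise: `response = 8 + 10 * ripeness + N(0, noiseSd)`
#' (a total-soluble-solids-like scale in percent, spanning 8–18 as fruit
#' ripen). Ground truth is returned for recovery tests.
#'
#' @param nSamples number of samples (>= 10).
#' @param noiseSd standard deviation of the response noise, response units.
#' @param seed integer seed for the response noise.
#' @param threshold saturation threshold for the spectra.
#' @param ... further arguments passed to [ripeningSeries()].
#' @return List with `predictors` (nSamples x 360 spectrum matrix),
#'   `response`, `ids`, and `groundTruth` (data.frame: ripeness, hue,
#'   saturation, hueBin).
#' @export
syntheticRegressionSet <- function(nSamples = 60L, noiseSd = 0.01,
                                   seed = 1L, threshold = 0.05, ...) {
  stopifnot(nSamples >= 10L)
  series <- ripeningSeries(nSamples, seed = seed, ...)
  spectra <- t(vapply(series,
    function(s) spectrumValues(computeHueSpectrum(s$image, threshold)),
    numeric(360)))
  colnames(spectra) <- paste0("h", 1:360)
  u <- vapply(series, `[[`, numeric(1), "ripeness")
  noise <- withr::with_seed(seed, stats::rnorm(nSamples, 0, noiseSd))
  list(predictors = spectra,
       response = 8 + 10 * u + noise,
       ids = sprintf("sample_%03d", seq_len(nSamples)),
       groundTruth = data.frame(
         ripeness = u,
         hue = vapply(series, `[[`, numeric(1), "hue"),
         saturation = vapply(series, `[[`, numeric(1), "saturation"),
         hueBin = vapply(series, `[[`, integer(1), "hueBin")))
}
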