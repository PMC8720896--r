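# Independent oracles used by several test files. These deliberately avoid
# the package's vectorized code paths.

# Naive per-pixel double-loop spectrum extraction: scalar arithmetic on one
# pixel at a time, integer conversion with half-away-from-zero rounding.
naiveHueSpectrum <- function(mpic, tv = 0.05, normalization = "included") {
  h <- dim(mpic)[1]; w <- dim(mpic)[2]
  fc <- integer(0); fs <- numeric(0)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      r <- as.numeric(mpic[i, j, 1])
      g <- as.numeric(mpic[i, j, 2])
      b <- as.numeric(mpic[i, j, 3])
      dx <- r - g / 2 - b / 2
      dy <- (g - b) * sqrt(3) / 2
      s <- sqrt(dx^2 + dy^2) / 255
      hh <- atan2(dy, dx) * 180 / pi
      if (hh < 0) hh <- hh + 360
      if (s > tv) {
        k <- floor(hh + 0.5)
        if (k == 0) k <- 360
        fc[length(fc) + 1L] <- k
        fs[length(fs) + 1L] <- s
      }
    }
  }
  rv <- numeric(360)
  n <- length(fc)
  if (n > 1) {
    for (t in seq_len(n)) rv[fc[t]] <- rv[fc[t]] + fs[t]
    div <- if (normalization == "included") n else h * w
    rv <- rv / div
  }
  rv
}

# Generic shoelace polygon centroid over an explicit closed vertex list.
polygonCentroidOracle <- function(xs, ys) {
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  cr <- xs * y2 - x2 * ys
  area <- sum(cr) / 2
  c(x = sum((xs + x2) * cr) / (6 * area),
    y = sum((ys + y2) * cr) / (6 * area),
    area = area)
}

pqsOracle <- function(v) {
  a <- (1:360) * 2 * pi / 360
  polygonCentroidOracle(v * cos(a), v * sin(a))
}

randomRGBImage <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}

uniformImage <- function(rgb, h = 4, w = 4) {
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}

circularShift <- function(v, k) v[((seq_along(v) - k - 1) %% length(v)) + 1]

rotatePoint <- function(x, y, theta)
  c(cos(theta) * x - sin(theta) * y, sin(theta) * x + cos(theta) * y)

# hue/saturation of a single RGB triple, scalar arithmetic
hueSatOfColor <- function(rgb) {
  dx <- rgb[1] - rgb[2] / 2 - rgb[3] / 2
  dy <- (rgb[2] - rgb[3]) * sqrt(3) / 2
  h <- atan2(dy, dx) * 180 / pi
  if (h < 0) h <- h + 360
  c(hue = h, sat = sqrt(dx^2 + dy^2) / 255)
}
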