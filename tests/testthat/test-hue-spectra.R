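# The saturation-weighted hue histogram and its spectrum operations.

test_that("uniform pure-red image concentrates all mass in the red bin", {
  img <- uniformImage(c(255, 0, 0), 10, 10)
  sp <- computeHueSpectrum(img, 0.05)
  expect_identical(spectrumValues(sp)[360], 1)
  expect_identical(sum(spectrumValues(sp)[-360]), 0)
  expect_identical(nIncluded(sp), 100)
  expect_identical(totalPixels(sp), 100)
})

test_that("neutral images yield an all-zero spectrum, not an error", {
  for (g in c(0, 127, 255)) {
    sp <- computeHueSpectrum(uniformImage(c(g, g, g), 10, 10))
    expect_identical(spectrumValues(sp), numeric(360))
    expect_identical(nIncluded(sp), 0)
  }
})

test_that("normalization divides by included pixels, not image size", {
  img <- uniformImage(c(255, 255, 255), 10, 10)
  img[, 1:5, 1] <- 255; img[, 1:5, 2] <- 0; img[, 1:5, 3] <- 0  # 50 red px
  sp <- computeHueSpectrum(img, 0.05)
  expect_identical(spectrumValues(sp)[360], 1)  # 50 * 1 / 50
  expect_identical(nIncluded(sp), 50)
  spTotal <- computeHueSpectrum(img, 0.05, normalization = "total")
  expect_identical(spectrumValues(spTotal)[360], 0.5)  # 50 * 1 / 100
})

test_that("a single included pixel gives the all-zero guard result", {
  img <- uniformImage(c(255, 255, 255), 5, 5)
  img[1, 1, ] <- c(255, 0, 0)
  sp <- computeHueSpectrum(img)
  expect_identical(spectrumValues(sp), numeric(360))
  expect_identical(nIncluded(sp), 1)
})

test_that("vectorized extraction equals the naive per-pixel transliteration", {
  set.seed(11)
  for (rep in 1:6) {
    img <- randomRGBImage(16, 16)
    for (mode in c("included", "total")) {
      sp <- computeHueSpectrum(img, 0.05, normalization = mode)
      expect_equal(spectrumValues(sp), naiveHueSpectrum(img, 0.05, mode),
                   tolerance = 1e-9)
    }
  }
})

test_that("bin mass balances the saturations of included pixels", {
  set.seed(12)
  img <- randomRGBImage(20, 20)
  sp <- computeHueSpectrum(img, 0.3)
  hs <- rgbToHueSat(img)
  satSum <- sum(hs$saturation[hs$saturation > 0.3])
  expect_equal(sum(spectrumValues(sp)) * nIncluded(sp), satSum,
               tolerance = 1e-9)
})

test_that("raising the threshold never admits more pixels", {
  set.seed(13)
  img <- randomRGBImage(24, 24)
  counts <- vapply(seq(0, 0.9, by = 0.1),
                   function(tv) nIncluded(computeHueSpectrum(img, tv)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tiling an image leaves its spectrum unchanged", {
  set.seed(14)
  img <- randomRGBImage(9, 9)
  tiled <- array(0, c(18, 18, 3))
  for (k in 1:3) {
    tiled[1:9, 1:9, k] <- img[, , k];  tiled[1:9, 10:18, k] <- img[, , k]
    tiled[10:18, 1:9, k] <- img[, , k]; tiled[10:18, 10:18, k] <- img[, , k]
  }
  for (mode in c("included", "total"))
    expect_equal(
      spectrumValues(computeHueSpectrum(tiled, normalization = mode)),
      spectrumValues(computeHueSpectrum(img, normalization = mode)),
      tolerance = 1e-12)
})

test_that("averaging spectra is the element-wise mean with matched metadata", {
  red <- computeHueSpectrum(uniformImage(c(255, 0, 0), 6, 6))
  green <- computeHueSpectrum(uniformImage(c(0, 255, 0), 6, 6))
  expect_equal(spectrumValues(averageSpectra(list(red, red))),
               spectrumValues(red))  # idempotence
  avg <- averageSpectra(list(red, green))
  expect_identical(avg@aggregate, TRUE)
  expect_equal(spectrumValues(avg)[360], 0.5)
  expect_equal(spectrumValues(avg)[120], 0.5)
  # k copies plus one zero spectrum scales by k/(k+1)
  zero <- computeHueSpectrum(uniformImage(c(255, 255, 255), 6, 6))
  k <- 3
  avgk <- averageSpectra(c(rep(list(red), k), list(zero)))
  expect_equal(spectrumValues(avgk), spectrumValues(red) * k / (k + 1),
               tolerance = 1e-12)
  expect_error(averageSpectra(list()), "non-empty")
  other <- computeHueSpectrum(uniformImage(c(255, 0, 0), 6, 6),
                              threshold = 0.2)
  expect_error(averageSpectra(list(red, other)), "different thresholds")
})

test_that("cropping keeps bins inside the (possibly wrapped) range", {
  red <- computeHueSpectrum(uniformImage(c(255, 0, 0), 6, 6))
  mixed <- HueSpectrum(replace(numeric(360), c(360, 120), c(1, 0.5)))
  expect_equal(spectrumValues(cropSpectrum(mixed, 1, 360)),
               spectrumValues(mixed))  # identity
  cr <- cropSpectrum(mixed, 90, 150)
  expect_identical(spectrumValues(cr)[120], 0.5)
  expect_identical(sum(spectrumValues(cr)), 0.5)
  wrapped <- cropSpectrum(mixed, 330, 30)
  expect_identical(spectrumValues(wrapped)[360], 1)
  expect_identical(spectrumValues(wrapped)[120], 0)
  expect_identical(cropRange(wrapped), c(330L, 30L))
  # brute-force membership over all bins for a wrapped range
  full <- HueSpectrum(rep(1, 360))
  keep <- spectrumValues(cropSpectrum(full, 300, 40)) > 0
  member <- vapply(1:360, function(d) d >= 300 || d <= 40, logical(1))
  expect_identical(keep, member)
  expect_error(cropSpectrum(mixed, 0, 10), "1..360")
  expect_error(cropSpectrum(mixed, 10, 400), "1..360")
})

test_that("peaks report circular location, height and interpolated FWHM", {
  v <- numeric(360); v[119:121] <- c(0.5, 1, 0.5)
  pk <- findPeaks(v)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$location, 120L)
  expect_identical(pk$height, 1)
  expect_equal(pk$width, 2)  # triangle: half max met exactly one bin away

  expect_identical(nrow(findPeaks(numeric(360))), 0L)

  v <- numeric(360); v[359] <- 0.4; v[360] <- 1; v[1] <- 0.4
  pk <- findPeaks(v)
  expect_identical(nrow(pk), 1L)  # detected once despite the wrap
  expect_identical(pk$location, 360L)

  # plateau resolves to its lowest degree
  v <- numeric(360); v[200:203] <- 0.8; v[c(199, 204)] <- 0.2
  expect_identical(findPeaks(v)$location, 200L)

  # minHeight filters
  v <- numeric(360); v[50] <- 0.3; v[250] <- 0.9
  expect_identical(findPeaks(v, minHeight = 0.5)$location, 250L)
  expect_identical(nrow(findPeaks(v, minHeight = 2)), 0L)
  expect_identical(nrow(findPeaks(rep(0.7, 360))), 0L)  # constant: no peak
})

test_that("FWHM of an asymmetric peak interpolates both flanks", {
  v <- numeric(360)
  v[100] <- 1; v[99] <- 0.75; v[98] <- 0.25; v[101] <- 0.2
  # left: crosses 0.5 between 99 (0.75) and 98 (0.25) -> 1 + 0.5 = 1.5
  # right: crosses between 100 (1) and 101 (0.2) -> 0.625
  pk <- findPeaks(v)
  expect_equal(pk$width, 1.5 + 0.625)
})
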