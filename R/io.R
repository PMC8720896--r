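# Reading raster images and reading/writing the package's CSV/JSON formats.
# CSV dialect is fixed: comma separator, '.' decimal, UTF-8, mandatory
# header row — independent of the locale.

#' Read a 24-bit RGB image
#'
#' Decodes PNG, JPEG or TIFF into an H x W x 3 array of integer intensities
#' in \[0, 255\]. An alpha channel is stripped with a warning; grayscale
#' input raises the non-color-image error; 16-bit TIFF is rejected unless
#' `rescale16 = TRUE`, which maps the 0–65535 range onto 0–255 explicitly.
#'
#' @param path image file path; format inferred from the extension.
#' @param rescale16 allow 16-bit TIFF input by rescaling to 8 bits.
#' @return H x W x 3 numeric array, values in \[0, 255\].
#' @export
readRGBImage <- function(path, rescale16 = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path) * 255,
    jpg = ,
    jpeg = jpeg::readJPEG(path) * 255,
    tif = ,
    tiff = {
      a <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(a, "bits.per.sample")
      if (!is.null(bits) && bits > 8 && !rescale16)
        stop("16-bit TIFF rejected; pass rescale16 = TRUE to map ",
             "0-65535 onto 0-255 explicitly")
      a * 255
    },
    stop("unsupported image format: '", ext,
         "' (PNG, JPEG and TIFF are supported)"))
  if (length(dim(arr)) == 2L) .nonColorError(path)
  nc <- dim(arr)[3L]
  if (nc == 4L) {
    warning("alpha channel stripped from ", path)
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (nc != 3L) {
    .nonColorError(path)
  }
  array(round(arr), dim(arr))
}

#' Write an RGB image as PNG
#'
#' @param image H x W x 3 numeric array, \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRGBImage <- function(image, path) {
  .checkRGBArray(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

.sidecarPath <- function(path)
  paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a hue spectrum as CSV plus JSON sidecar
#'
#' The CSV has the header `degree,value` and 360 rows, labelling bins by
#' degree to avoid off-by-one ambiguity; values are written with 15
#' significant digits so the round trip is lossless well past 12 digits.
#' The sidecar (same path with `.json` extension) stores threshold,
#' included/total pixel counts, normalization mode, crop range and the
#' aggregate flag.
#'
#' @param spectrum a [HueSpectrum-class].
#' @param path CSV output path.
#' @return `writeSpectrum`: `path` invisibly; `readSpectrum`: the
#'   reconstructed [HueSpectrum-class].
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "HueSpectrum"))
  lines <- c("degree,value",
             sprintf("%d,%.15g", 1:360, spectrum@values))
  writeLines(lines, path, useBytes = TRUE)
  meta <- list(threshold = spectrum@threshold,
               n_included = spectrum@nIncluded,
               total_pixels = spectrum@totalPixels,
               normalization = spectrum@normalization,
               crop_range = if (length(spectrum@cropRange))
                 spectrum@cropRange else NULL,
               aggregate = spectrum@aggregate)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  tab <- utils::read.csv(path, colClasses = c("integer", "numeric"))
  if (!identical(names(tab), c("degree", "value")) || nrow(tab) != 360L)
    stop("malformed spectrum CSV: expected header 'degree,value' and ",
         "360 rows in ", path)
  vals <- numeric(360)
  vals[tab$degree] <- tab$value
  side <- .sidecarPath(path)
  if (!file.exists(side)) stop("missing spectrum sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  HueSpectrum(vals, nIncluded = meta$n_included,
              totalPixels = meta$total_pixels, threshold = meta$threshold,
              normalization = meta$normalization,
              cropRange = if (is.null(meta$crop_range)) integer(0)
                          else as.integer(meta$crop_range),
              aggregate = isTRUE(meta$aggregate))
}

#' Write / read a spectra matrix (one row per image)
#'
#' Header `id,h1,...,h360`; each row holds one image's 360 bin values.
#'
#' @param spectra matrix n x 360, or list of [HueSpectrum-class].
#' @param ids character ids, one per row.
#' @param path CSV path.
#' @return `writeSpectraMatrix`: `path` invisibly; `readSpectraMatrix`: a
#'   list with `ids` and the numeric `spectra` matrix.
#' @export
writeSpectraMatrix <- function(spectra, ids, path) {
  if (is.list(spectra))
    spectra <- t(vapply(spectra, spectrumValues, numeric(360)))
  stopifnot(ncol(spectra) == 360L, nrow(spectra) == length(ids))
  header <- paste(c("id", paste0("h", 1:360)), collapse = ",")
  rows <- vapply(seq_len(nrow(spectra)), function(i)
    paste(c(ids[i], sprintf("%.15g", spectra[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeSpectraMatrix
#' @export
readSpectraMatrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[1L] != "id" || ncol(tab) != 361L)
    stop("malformed spectra matrix CSV: expected columns id,h1..h360 in ",
         path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- names(tab)[-1L][!vapply(tab[-1L], is.numeric, logical(1))]
    stop("non-numeric spectrum columns in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  storage.mode(m) <- "double"
  list(ids = as.character(tab$id), spectra = m)
}

#' Write PQS points as CSV
#'
#' One row per spectrum: `id,lo,hi,pqs_x,pqs_y,area`. Undefined points
#' (zero-area polar figure) are written as `NA` with the reason in a
#' `note` column.
#'
#' @param points list of [PQSPoint-class] or `NULL` for undefined points.
#' @param ids character ids.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writePQSTable <- function(points, ids, path) {
  stopifnot(length(points) == length(ids))
  rows <- vapply(seq_along(points), function(i) {
    p <- points[[i]]
    if (is.null(p))
      sprintf("%s,NA,NA,NA,NA,NA,zero-area polar figure", ids[i])
    else
      sprintf("%s,%d,%d,%.15g,%.15g,%.15g,", ids[i],
              p@range[1L], p@range[2L], p@x, p@y, p@area)
  }, character(1))
  writeLines(c("id,lo,hi,pqs_x,pqs_y,area,note", rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a regression dataset CSV
#'
#' Expected columns: `id`, `response`, then the predictor block — either 360
#' spectrum bins (`h1..h360`) or 6 RGB statistics
#' (`mean_r,mean_g,mean_b,sd_r,sd_g,sd_b`).
#'
#' @param path CSV path.
#' @return List with `ids`, `response`, `predictors` (numeric matrix).
#' @export
readRegressionDataset <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("id", "response")
  if (!all(need %in% names(tab)[1:2]))
    stop("malformed dataset CSV: first columns must be id,response in ", path)
  pred <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(pred) <- "double"
  if (anyNA(pred) || anyNA(tab$response))
    stop("dataset contains missing values: ", path)
  list(ids = as.character(tab$id), response = as.numeric(tab$response),
       predictors = pred)
}

#' Write a regression dataset CSV
#'
#' @param ids,response,predictors dataset components as returned by
#'   [syntheticRegressionSet()] (predictors may be the spectrum matrix or an
#'   RGB-feature matrix).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeRegressionDataset <- function(ids, response, predictors, path) {
  stopifnot(length(ids) == length(response),
            nrow(predictors) == length(ids))
  cn <- colnames(predictors)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(predictors)))
  header <- paste(c("id", "response", cn), collapse = ",")
  rows <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], sprintf("%.15g", response[i]),
            sprintf("%.15g", predictors[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Serialize a fit report as JSON
#'
#' @param fit a [QualityFit-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fit, path) {
  stopifnot(is(fit, "QualityFit"))
  jsonlite::write_json(fitReport(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
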