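#' Calibrated 8-bit brightfield image
#'
#' Container for a single-channel histology raster together with its physical
#' pixel size. Intensities follow the brightfield convention: higher values are
#' brighter, so white adipocyte lumina sit near 255 and stained membranes are
#' dark. All downstream geometry (areas, perimeters) is expressed in microns
#' via `microns_per_pixel`.
#'
#' @param pixels Integer matrix of intensities in `[0, 255]`; rows are image
#'   rows (y), columns are x.
#' @param microns_per_pixel Physical pixel edge length in micrometres
#'   (isotropic). A length-2 vector is accepted only if both entries are
#'   equal; anisotropic rasters are rejected.
#'
#' @return An object of class `calibrated_image`: a list with elements
#'   `pixels` (integer matrix) and `microns_per_pixel` (scalar). One pixel
#'   covers `microns_per_pixel^2` square microns.
#' @export
#' @examples
#' img <- calibrated_image(matrix(255L, 4, 4), microns_per_pixel = 0.5)
#' dim(img)
calibrated_image <- function(pixels, microns_per_pixel) {
  if (!is.matrix(pixels)) {
    abort("`pixels` must be a matrix of 8-bit intensities.")
  }
  if (length(microns_per_pixel) == 2L) {
    if (!isTRUE(all.equal(microns_per_pixel[[1]], microns_per_pixel[[2]]))) {
      abort("Anisotropic pixels are not supported: the two pixel sizes differ.")
    }
    microns_per_pixel <- microns_per_pixel[[1]]
  }
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    abort("`microns_per_pixel` must be a single positive number.")
  }
  if (anyNA(pixels)) abort("`pixels` contains missing values.")
  if (is.double(pixels)) {
    if (max(abs(pixels - round(pixels))) > 1e-8) {
      abort("`pixels` must hold 8-bit integer intensities (no fractional values).")
    }
    pixels <- round(pixels)
  }
  storage.mode(pixels) <- "integer"
  rng <- range(pixels)
  if (rng[1] < 0L || rng[2] > 255L) {
    abort("Intensities must lie in [0, 255].")
  }
  structure(
    list(pixels = pixels, microns_per_pixel = as.numeric(microns_per_pixel)),
    class = "calibrated_image"
  )
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<calibrated_image> %d x %d px at %.4g um/px (%.4g x %.4g um)\n",
    d[2], d[1], x$microns_per_pixel,
    d[2] * x$microns_per_pixel, d[1] * x$microns_per_pixel
  ))
  invisible(x)
}

is_calibrated_image <- function(x) inherits(x, "calibrated_image")

assert_image <- function(img, arg = "img") {
  if (!is_calibrated_image(img)) {
    abort(sprintf("`%s` must be a `calibrated_image` (see `calibrated_image()`).", arg))
  }
  img
}

#' Convert an RGB raster to grayscale luminance
#'
#' Collapses a 3-channel 8-bit raster to the standard Rec. 601 luminance
#' `0.299 R + 0.587 G + 0.114 B`, rounded half-up to an integer. All intensity
#' thresholds in this package are single-channel, so RGB input is converted
#' before any analysis.
#'
#' @param rgb A `height x width x 3` array with 8-bit integer values in
#'   `[0, 255]`.
#' @param microns_per_pixel Physical pixel size in micrometres.
#'
#' @return A grayscale [calibrated_image()].
#' @export
#' @examples
#' px <- array(c(100, 150, 200), dim = c(1, 1, 3))
#' to_grayscale(px, 1)$pixels  # 141
to_grayscale <- function(rgb, microns_per_pixel) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    abort("`rgb` must be a height x width x 3 array.")
  }
  if (anyNA(rgb)) abort("`rgb` contains missing values.")
  if (min(rgb) < 0 || max(rgb) > 255 || max(abs(rgb - round(rgb))) > 1e-8) {
    abort("`rgb` must hold 8-bit integer channel values in [0, 255].")
  }
  lum <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  lum <- pmin(pmax(floor(lum + 0.5), 0), 255)
  calibrated_image(matrix(lum, dim(rgb)[1], dim(rgb)[2]), microns_per_pixel)
}

# block mean over row-blocks of size f (nrow must be a multiple of f)
.block_rows <- function(m, f) {
  nr2 <- nrow(m) / f
  matrix(colMeans(matrix(m, nrow = f)), nrow = nr2)
}

#' Downsample a calibrated image by block averaging
#'
#' Reduces resolution by an integer factor using block means (an antialiasing
#' reduction that preserves thin membranes better than decimation), rounding
#' half-up to 8-bit integers. The pixel size is multiplied by the factor so the
#' physical extent is preserved to within one block; trailing rows/columns that
#' do not complete a block are dropped.
#'
#' @param img A [calibrated_image()].
#' @param factor Integer reduction factor, at least 1.
#'
#' @return A [calibrated_image()] with `microns_per_pixel` scaled by `factor`.
#' @export
downsample <- function(img, factor) {
  assert_image(img)
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 1 || factor != round(factor)) {
    abort("`factor` must be a single integer >= 1.")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  d <- dim(img$pixels)
  nr2 <- d[1] %/% factor
  nc2 <- d[2] %/% factor
  if (nr2 < 1L || nc2 < 1L) {
    abort("`factor` exceeds the image dimensions.")
  }
  m <- img$pixels[seq_len(nr2 * factor), seq_len(nc2 * factor), drop = FALSE]
  m <- t(.block_rows(t(.block_rows(m, factor)), factor))
  calibrated_image(floor(m + 0.5), img$microns_per_pixel * factor)
}

#' Crop a rectangular field from a slide
#'
#' Extracts a sub-image with the same pixel calibration, emulating the limited
#' field of view of a camera micrograph taken from a whole slide.
#'
#' @param img A [calibrated_image()].
#' @param field_w_px,field_h_px Field width and height in pixels.
#' @param origin Length-2 integer vector `c(x, y)`: the 1-based top-left corner
#'   of the field.
#'
#' @return A [calibrated_image()] of the requested size.
#' @export
crop_field <- function(img, field_w_px, field_h_px, origin = c(1L, 1L)) {
  assert_image(img)
  d <- dim(img$pixels)
  x0 <- origin[[1]]
  y0 <- origin[[2]]
  if (x0 < 1 || y0 < 1 || x0 + field_w_px - 1 > d[2] || y0 + field_h_px - 1 > d[1]) {
    abort("Requested field falls outside the image.")
  }
  calibrated_image(
    img$pixels[y0:(y0 + field_h_px - 1), x0:(x0 + field_w_px - 1), drop = FALSE],
    img$microns_per_pixel
  )
}

#' Crop a centred field from a slide
#'
#' Convenience wrapper around [crop_field()] that centres the field on the
#' image, the deterministic choice used when emulating micrograph acquisition
#' from synthetic slides.
#'
#' @inheritParams crop_field
#' @return A [calibrated_image()].
#' @export
crop_center <- function(img, field_w_px, field_h_px) {
  d <- dim(img$pixels)
  if (field_w_px > d[2] || field_h_px > d[1]) {
    abort("Requested field is larger than the image.")
  }
  x0 <- (d[2] - field_w_px) %/% 2 + 1L
  y0 <- (d[1] - field_h_px) %/% 2 + 1L
  crop_field(img, field_w_px, field_h_px, origin = c(x0, y0))
}

#' Read a calibrated image from TIFF or PNG
#'
#' Reads an 8-bit grayscale or RGB raster (TIFF, including LZW-compressed, or
#' PNG) and attaches the user-supplied pixel calibration. Scanner magnification
#' does not determine the physical pixel size, so `microns_per_pixel` must be
#' given explicitly. RGB input is converted with [to_grayscale()].
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param microns_per_pixel Physical pixel size in micrometres.
#'
#' @return A grayscale [calibrated_image()].
#' @export
read_calibrated_image <- function(path, microns_per_pixel) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(sprintf("Unsupported image format '.%s' (use TIFF or PNG).", ext))
  )
  vals <- round(raw * 255)
  nd <- length(dim(vals))
  if (nd == 2L) {
    calibrated_image(vals, microns_per_pixel)
  } else if (nd == 3L && dim(vals)[3] >= 3L) {
    to_grayscale(vals[, , 1:3, drop = FALSE], microns_per_pixel)
  } else if (nd == 3L && dim(vals)[3] == 1L) {
    calibrated_image(vals[, , 1], microns_per_pixel)
  } else {
    abort("Unsupported channel layout; expected grayscale or RGB.")
  }
}

#' Write an image or binary mask to TIFF or PNG
#'
#' Writes a [calibrated_image()], intensity matrix, or logical mask as an
#' 8-bit grayscale file. TIFF output uses LZW compression. Masks are written
#' with foreground = 255.
#'
#' @param x A [calibrated_image()], a numeric matrix in `[0, 255]`, or a
#'   logical matrix.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#'
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(x, path) {
  if (is_calibrated_image(x)) x <- x$pixels
  if (is.logical(x)) x <- x * 255L
  m <- x / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "LZW"),
    png = png::writePNG(m, path),
    abort(sprintf("Unsupported image format '.%s' (use TIFF or PNG).", ext))
  )
  invisible(path)
}
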