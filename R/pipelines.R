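# Binary morphology helpers over EBImage, keeping everything as R matrices.
.dilate_mask <- function(mask, brush_size) {
  if (brush_size <= 1L) return(mask)
  out <- EBImage::dilate(mask * 1L, EBImage::makeBrush(brush_size, shape = "box"))
  out > 0.5
}

.close_mask <- function(mask, radius_px) {
  if (radius_px < 1L) return(mask)
  out <- EBImage::closing(mask * 1L, EBImage::makeBrush(2L * radius_px + 1L, shape = "disc"))
  out > 0.5
}

.fill_holes <- function(mask) {
  EBImage::fillHull(mask * 1L) > 0.5
}

# Drop connected components smaller than min_px (8-connectivity).
.drop_small <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity = 8)
  n <- n_labels(lab)
  if (n == 0L) return(mask)
  keep <- tabulate(lab[lab > 0L], nbins = n) >= min_px
  matrix(c(FALSE, keep)[lab + 1L], nrow(mask), ncol(mask))
}

empty_detections <- function(pipeline) {
  tibble(
    pipeline = character(), label = integer(), area_um2 = double(),
    perimeter_um = double(), circularity = double(),
    centroid_x_px = double(), centroid_y_px = double()
  )
}

.finish_detections <- function(labels, img, filters, pipeline) {
  det <- measure_particles(labels, img$microns_per_pixel)
  det <- filter_particles(det, filters)
  dplyr::bind_cols(tibble(pipeline = rep(pipeline, nrow(det))), det)
}

.resolve_tissue <- function(img, tissue, pipeline) {
  if (is.null(tissue)) {
    return(matrix(TRUE, nrow(img$pixels), ncol(img$pixels)))
  }
  if (!is.matrix(tissue) || !all(dim(tissue) == dim(img$pixels))) {
    abort("`tissue` must be a mask with the same dimensions as the image.")
  }
  if (!any(tissue)) {
    warn(sprintf("Tissue mask is empty; %s pipeline returns no detections.", pipeline))
  }
  tissue > 0
}

#' Sobel "find edges" pass
#'
#' One pass of the classic 3x3 Sobel gradient magnitude with replicated
#' borders, linearly rescaled so the strongest edge maps to 255 (rounded
#' half-up). Matches the behaviour of the ImageJ Find Edges command that the
#' edge-based pipeline iterates.
#'
#' @param pixels Numeric matrix of intensities.
#' @return Numeric matrix of edge magnitudes in `[0, 255]`.
#' @export
find_edges <- function(pixels) {
  nr <- nrow(pixels)
  nc <- ncol(pixels)
  p <- rbind(pixels[1, , drop = FALSE], pixels, pixels[nr, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, nc, drop = FALSE])
  rows <- 2:(nr + 1)
  cols <- 2:(nc + 1)
  NW <- p[rows - 1, cols - 1]; N <- p[rows - 1, cols]; NE <- p[rows - 1, cols + 1]
  W  <- p[rows, cols - 1];                              E  <- p[rows, cols + 1]
  SW <- p[rows + 1, cols - 1]; S <- p[rows + 1, cols]; SE <- p[rows + 1, cols + 1]
  gx <- (NW + 2 * W + SW) - (NE + 2 * E + SE)
  gy <- (NW + 2 * N + NE) - (SW + 2 * S + SE)
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(0, nr, nc))
  floor(mag * (255 / mx) + 0.5)
}

#' Otsu threshold of an 8-bit intensity matrix
#'
#' @param pixels Numeric matrix with values in `[0, 255]`.
#' @return The Otsu threshold on the 0-255 scale.
#' @export
otsu_threshold <- function(pixels) {
  EBImage::otsu(pixels / 255, range = c(0, 1), levels = 256L) * 255
}

#' Tissue detection parameters
#'
#' Settings for [detect_tissue()], which excludes extraneous whitespace before
#' whole-slide analysis. Brightfield whitespace is near-saturated, so pixels at
#' or above `whitespace_min_intensity` are treated as background. The vendor
#' defaults used in the original workflows are not published; these defaults
#' are this package's own and are fully configurable.
#'
#' @param whitespace_min_intensity Minimum intensity regarded as whitespace
#'   (default 245).
#' @param min_tissue_fragment_um2 Tissue fragments smaller than this are
#'   discarded as debris (default 1e4 um^2, i.e. anything smaller than a few
#'   dozen adipocytes).
#' @param closing_radius_px Radius of the morphological closing applied to the
#'   tissue mask (default 5 px).
#'
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(whitespace_min_intensity = 245,
                          min_tissue_fragment_um2 = 1e4,
                          closing_radius_px = 5) {
  if (whitespace_min_intensity < 0 || whitespace_min_intensity > 255) {
    abort("`whitespace_min_intensity` must lie in [0, 255].")
  }
  structure(
    list(
      whitespace_min_intensity = whitespace_min_intensity,
      min_tissue_fragment_um2 = min_tissue_fragment_um2,
      closing_radius_px = as.integer(closing_radius_px)
    ),
    class = "tissue_params"
  )
}

#' Detect tissue and exclude whitespace
#'
#' Builds a binary tissue mask: pixels darker than the whitespace threshold,
#' morphologically closed, with small fragments removed, and with enclosed
#' holes filled so that bright adipocyte lumina inside tissue remain
#' analysable.
#'
#' @param img A grayscale [calibrated_image()].
#' @param params A [tissue_params()] object.
#'
#' @return A logical matrix, `TRUE` on tissue.
#' @export
detect_tissue <- function(img, params = tissue_params()) {
  assert_image(img)
  mask <- img$pixels < params$whitespace_min_intensity
  if (!any(mask)) return(mask)
  mask <- .close_mask(mask, params$closing_radius_px)
  min_px <- ceiling(params$min_tissue_fragment_um2 / img$microns_per_pixel^2)
  mask <- .drop_small(mask, min_px)
  .fill_holes(mask)
}

#' Edge-based whole-slide pipeline parameters
#'
#' The open-source whole-slide workflow: the Sobel "find edges" pass is run
#' `n_edge_passes` times (default 3), the edge image is binarised, and the
#' enclosed non-edge interiors (the lumina) become candidate particles that
#' are filtered by area and circularity.
#'
#' @param n_edge_passes Number of Find Edges passes (default 3).
#' @param binarize_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold on the 0-255 edge-magnitude scale, used
#'   when `binarize_method = "fixed"`; pixels at or below it are candidate
#'   interior.
#' @param filters A [filter_params()] object; defaults to area 500-20,000 um^2
#'   and circularity 0.3-1.0.
#'
#' @return An object of class `edge_params`.
#' @export
edge_params <- function(n_edge_passes = 3,
                        binarize_method = c("otsu", "fixed"),
                        fixed_threshold = 128,
                        filters = filter_params(circ_min = 0.3, circ_max = 1.0)) {
  if (n_edge_passes < 1) abort("`n_edge_passes` must be >= 1.")
  structure(
    list(
      n_edge_passes = as.integer(n_edge_passes),
      binarize_method = match.arg(binarize_method),
      fixed_threshold = fixed_threshold,
      filters = filters
    ),
    class = "edge_params"
  )
}

#' Threshold-based whole-slide pipeline parameters
#'
#' The intensity-threshold workflow: pixels with intensities 0-230 are
#' classified as membrane and 231-255 as fat; fat objects smaller than
#' `noise_min_px` are discarded as noise; membrane specks fully enclosed in a
#' fat object are filled; surviving particles are filtered by area and
#' perimeter (perimeter standing proxy for circularity).
#'
#' @param membrane_max Upper membrane intensity (default 230); fat starts at
#'   `membrane_max + 1`.
#' @param noise_min_px Minimum object size, in pixels, treated as signal
#'   (default 50).
#' @param fill_holes Fill enclosed membrane specks inside fat objects
#'   (default `TRUE`).
#' @param filters A [filter_params()] object; defaults to area 500-20,000 um^2
#'   and perimeter 0-900 um.
#'
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(membrane_max = 230, noise_min_px = 50,
                             fill_holes = TRUE,
                             filters = filter_params(perim_min_um = 0, perim_max_um = 900)) {
  if (membrane_max < 0 || membrane_max > 254) {
    abort("`membrane_max` must lie in [0, 254].")
  }
  structure(
    list(
      membrane_max = membrane_max,
      noise_min_px = as.integer(noise_min_px),
      fill_holes = isTRUE(fill_holes),
      filters = filters
    ),
    class = "threshold_params"
  )
}

#' Micrograph pipeline parameters
#'
#' The conventional single-field workflow: a percentile threshold separates
#' stained membrane from bright lumina, the membrane mask is dilated
#' `n_dilates` times with a 3x3 structuring element to close gaps between
#' membrane segments, and the remaining components are filtered by area only.
#'
#' @param percentile Fraction of pixels at or below the threshold
#'   (default 0.5, the ImageJ Percentile default). On tissue whose stained
#'   fraction differs from one half, set this near the image's actual membrane
#'   pixel fraction.
#' @param n_dilates Number of 3x3 binary dilations of the membrane mask
#'   (default 10).
#' @param filters A [filter_params()] object; defaults to area 500-20,000 um^2
#'   only.
#'
#' @return An object of class `micrograph_params`.
#' @export
micrograph_params <- function(percentile = 0.5, n_dilates = 10,
                              filters = filter_params()) {
  if (percentile <= 0 || percentile >= 1) {
    abort("`percentile` must lie strictly between 0 and 1.")
  }
  if (n_dilates < 0) abort("`n_dilates` must be >= 0.")
  structure(
    list(
      percentile = percentile,
      n_dilates = as.integer(n_dilates),
      filters = filters
    ),
    class = "micrograph_params"
  )
}

#' Classify 8-bit intensities as membrane or fat
#'
#' The classification stage of the threshold pipeline: intensities from 0 to
#' `membrane_max` are membrane, from `membrane_max + 1` to 255 are fat.
#'
#' @param intensities Integer vector in `[0, 255]`.
#' @param membrane_max Upper membrane intensity (default 230).
#'
#' @return Character vector of `"membrane"` / `"fat"`.
#' @export
#' @examples
#' classify_membrane_fat(c(0, 230, 231, 255))
classify_membrane_fat <- function(intensities, membrane_max = 230) {
  ifelse(intensities <= membrane_max, "membrane", "fat")
}

#' Edge-based whole-slide segmentation
#'
#' Runs the Sobel "find edges" pass `n_edge_passes` times, binarises the edge
#' image (Otsu by default), and takes the below-threshold non-edge interiors -
#' the enclosed lumina - as candidate particles within the tissue mask.
#' Candidates are labelled (8-connectivity), measured, and filtered by area
#' and circularity.
#'
#' @param img A grayscale [calibrated_image()].
#' @param params An [edge_params()] object.
#' @param tissue Optional logical tissue mask from [detect_tissue()]; `NULL`
#'   analyses the full frame.
#'
#' @return A detection tibble: `pipeline`, `label`, `area_um2`,
#'   `perimeter_um`, `circularity`, `centroid_x_px`, `centroid_y_px`.
#' @export
segment_edge <- function(img, params = edge_params(), tissue = NULL) {
  assert_image(img)
  stopifnot(inherits(params, "edge_params"))
  tissue <- .resolve_tissue(img, tissue, "edge")
  if (!any(tissue)) return(empty_detections("edge"))

  g <- img$pixels * 1.0
  for (i in seq_len(params$n_edge_passes)) g <- find_edges(g)
  if (max(g) == 0) {
    warn("Image has no gradients; edge pipeline returns no detections.")
    return(empty_detections("edge"))
  }
  thr <- switch(params$binarize_method,
    otsu = otsu_threshold(g),
    fixed = params$fixed_threshold
  )
  fg <- (g <= thr) & tissue
  if (!any(fg)) return(empty_detections("edge"))
  lab <- label_components(fg, connectivity = 8)
  .finish_detections(lab, img, params$filters, "edge")
}

#' Threshold-based whole-slide segmentation
#'
#' Classifies pixels as membrane (0 to `membrane_max`) or fat
#' (`membrane_max + 1` to 255), restricts fat to the tissue mask, removes fat
#' objects smaller than `noise_min_px`, optionally fills membrane specks fully
#' enclosed by a fat object, then labels, measures, and filters by area and
#' perimeter.
#'
#' @param img A grayscale [calibrated_image()].
#' @param params A [threshold_params()] object.
#' @param tissue Optional logical tissue mask from [detect_tissue()]; `NULL`
#'   analyses the full frame.
#'
#' @return A detection tibble (see [segment_edge()]).
#' @export
segment_threshold <- function(img, params = threshold_params(), tissue = NULL) {
  assert_image(img)
  stopifnot(inherits(params, "threshold_params"))
  tissue <- .resolve_tissue(img, tissue, "threshold")
  if (!any(tissue)) return(empty_detections("threshold"))

  fat <- (img$pixels >= params$membrane_max + 1) & tissue
  fat <- .drop_small(fat, params$noise_min_px)
  if (params$fill_holes) fat <- .fill_holes(fat)
  if (!any(fat)) return(empty_detections("threshold"))
  lab <- label_components(fat, connectivity = 8)
  .finish_detections(lab, img, params$filters, "threshold")
}

#' Micrograph segmentation of a single field
#'
#' Percentile thresholding: the threshold is the smallest intensity whose
#' cumulative pixel fraction reaches `percentile`. Pixels above the threshold
#' form the lumen mask; its complement (the membrane) is dilated `n_dilates`
#' times with a 3x3 element to close gaps between adjacent cell membranes;
#' the components of the remaining non-membrane area are measured and filtered
#' by area. Dilation shrinks each lumen, so measured areas are biased low
#' relative to truth - the documented behaviour of this conventional method.
#'
#' @param img A grayscale [calibrated_image()] covering one field of view.
#' @param params A [micrograph_params()] object.
#'
#' @return A detection tibble (see [segment_edge()]).
#' @export
segment_micrograph <- function(img, params = micrograph_params()) {
  assert_image(img)
  stopifnot(inherits(params, "micrograph_params"))
  h <- tabulate(img$pixels + 1L, nbins = 256L)
  cum <- cumsum(h) / sum(h)
  thr <- which(cum >= params$percentile)[1] - 1L
  lumen <- img$pixels > thr
  if (!any(lumen)) {
    warn("Degenerate intensity histogram (no pixels above the percentile threshold); micrograph pipeline returns no detections.")
    return(empty_detections("micrograph"))
  }
  membrane <- !lumen
  if (params$n_dilates > 0L) {
    membrane <- .dilate_mask(membrane, 2L * params$n_dilates + 1L)
  }
  fg <- !membrane
  if (!any(fg)) {
    warn("Membrane dilation covered the whole field; micrograph pipeline returns no detections.")
    return(empty_detections("micrograph"))
  }
  lab <- label_components(fg, connectivity = 8)
  .finish_detections(lab, img, params$filters, "micrograph")
}
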