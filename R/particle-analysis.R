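#' Label connected components of a binary mask
#'
#' Connected-component labelling, the engine behind "analyze particles" style
#' segmentation. Foreground pixels sharing a 4- or 8-neighbourhood path get the
#' same label; labels are renumbered `1..n_labels` in raster-scan (row-major)
#' order of each component's first pixel, so labelling is deterministic.
#'
#' @param mask Logical matrix, or numeric/integer matrix containing only 0 and
#'   1. Any other values are rejected.
#' @param connectivity 8 (default; the ImageJ particle convention) or 4.
#'
#' @return An integer matrix of labels (0 = background) with attributes
#'   `n_labels` and `connectivity`.
#' @export
#' @examples
#' m <- matrix(0L, 5, 5); m[1:2, 1:2] <- 1L; m[3:4, 3:4] <- 1L
#' attr(label_components(m, 4), "n_labels")  # 2
#' attr(label_components(m, 8), "n_labels")  # 1
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  if (is.logical(mask)) {
    if (anyNA(mask)) abort("`mask` contains missing values.")
    m <- mask * 1L
  } else {
    if (anyNA(mask) || !all(mask %in% c(0, 1))) {
      abort("`mask` must be strictly binary (0/1 or logical).")
    }
    m <- mask
    storage.mode(m) <- "integer"
  }
  lab <- .cc_label(m, as.integer(connectivity))
  attr(lab, "connectivity") <- as.integer(connectivity)
  lab
}

#' Number of labels in a label matrix
#' @param labels An integer label matrix from [label_components()].
#' @return Integer count of distinct positive labels.
#' @export
n_labels <- function(labels) {
  n <- attr(labels, "n_labels")
  if (is.null(n)) n <- max(0L, max(labels))
  as.integer(n)
}

# Per-label geometry for an integer label matrix (labels need not be
# consecutive; labels with zero pixels are dropped). Perimeter follows the
# crack-boundary convention: the count of pixel edges exposed to a different
# label or to background, including the image border. Centroids are mean pixel
# coordinates, 1-based, x = column, y = row.
measure_label_matrix <- function(labels, microns_per_pixel) {
  nmax <- max(0L, max(labels))
  if (nmax == 0L) {
    return(tibble(
      label = integer(), area_um2 = double(), perimeter_um = double(),
      circularity = double(), centroid_x_px = double(), centroid_y_px = double()
    ))
  }
  nr <- nrow(labels)
  nc <- ncol(labels)
  area_px <- tabulate(labels[labels > 0L], nbins = nmax)

  zr <- matrix(0L, nr, 1L)
  zc <- matrix(0L, 1L, nc)
  exposed_count <- function(shifted) {
    idx <- labels > 0L & labels != shifted
    tabulate(labels[idx], nbins = nmax)
  }
  per_px <- exposed_count(cbind(labels[, -1, drop = FALSE], zr)) + # right
    exposed_count(cbind(zr, labels[, -nc, drop = FALSE])) +        # left
    exposed_count(rbind(labels[-1, , drop = FALSE], zc)) +         # down
    exposed_count(rbind(zc, labels[-nr, , drop = FALSE]))          # up

  fg <- which(labels > 0L)
  lab <- labels[fg]
  ai <- arrayInd(fg, dim(labels))
  sums <- rowsum(cbind(y = ai[, 1], x = ai[, 2]), group = lab)
  ids <- as.integer(rownames(sums))

  s <- microns_per_pixel
  keep <- area_px[ids] > 0L
  ids <- ids[keep]
  area <- area_px[ids] * s^2
  per <- per_px[ids] * s
  tibble(
    label = ids,
    area_um2 = area,
    perimeter_um = per,
    circularity = pmin(1, 4 * pi * area / per^2),
    centroid_x_px = sums[keep, "x"] / area_px[ids],
    centroid_y_px = sums[keep, "y"] / area_px[ids]
  )
}

#' Measure labelled particles
#'
#' Computes per-particle geometry in physical units from a label matrix:
#' area (pixel count times `microns_per_pixel^2`), perimeter under the
#' crack-boundary convention (count of exposed pixel edges times
#' `microns_per_pixel`), circularity `min(1, 4 * pi * area / perimeter^2)`,
#' and the centroid in pixel coordinates. Digitisation can push the raw
#' circularity of near-disks above 1, and the inclusion filters treat 1.0 as
#' the upper bound, so circularity is capped at 1.
#'
#' @param labels Integer label matrix from [label_components()].
#' @param microns_per_pixel Physical pixel size in micrometres.
#'
#' @return A tibble with one row per particle: `label`, `area_um2`,
#'   `perimeter_um`, `circularity`, `centroid_x_px`, `centroid_y_px`.
#' @export
#' @examples
#' m <- matrix(0L, 12, 12); m[2:11, 2:11] <- 1L
#' measure_particles(label_components(m), 1)  # area 100, perimeter 40
measure_particles <- function(labels, microns_per_pixel) {
  if (!is.matrix(labels)) abort("`labels` must be an integer label matrix.")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0) {
    abort("`microns_per_pixel` must be positive.")
  }
  measure_label_matrix(labels, microns_per_pixel)
}

#' Particle inclusion windows
#'
#' The closed inclusion intervals applied to candidate particles. Defaults
#' follow the study design: area 500-20,000 um^2 in every pipeline; the
#' edge-based pipeline adds circularity 0.3-1.0; the threshold pipeline adds
#' perimeter 0-900 um (a proxy for circularity). A bound set to `NULL`
#' deactivates that filter. All bounds are inclusive: a 500 um^2, circularity
#' 0.30 particle is retained.
#'
#' @param area_min_um2,area_max_um2 Area window in square micrometres.
#' @param circ_min,circ_max Circularity window within `[0, 1]`, or `NULL`.
#' @param perim_min_um,perim_max_um Perimeter window in micrometres, or `NULL`.
#'
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(area_min_um2 = 500, area_max_um2 = 20000,
                          circ_min = NULL, circ_max = NULL,
                          perim_min_um = NULL, perim_max_um = NULL) {
  if (!is.null(area_min_um2) && !is.null(area_max_um2) &&
      area_min_um2 >= area_max_um2) {
    abort("`area_min_um2` must be smaller than `area_max_um2`.")
  }
  if (xor(is.null(circ_min), is.null(circ_max))) {
    abort("Set both or neither of `circ_min`, `circ_max`.")
  }
  if (!is.null(circ_min)) {
    if (circ_min < 0 || circ_max > 1 || circ_min > circ_max) {
      abort("Circularity bounds must satisfy 0 <= circ_min <= circ_max <= 1.")
    }
  }
  if (xor(is.null(perim_min_um), is.null(perim_max_um))) {
    abort("Set both or neither of `perim_min_um`, `perim_max_um`.")
  }
  if (!is.null(perim_min_um) && perim_min_um > perim_max_um) {
    abort("`perim_min_um` must not exceed `perim_max_um`.")
  }
  structure(
    list(
      area_min_um2 = area_min_um2, area_max_um2 = area_max_um2,
      circ_min = circ_min, circ_max = circ_max,
      perim_min_um = perim_min_um, perim_max_um = perim_max_um
    ),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  fmt <- function(lo, hi, unit) {
    if (is.null(lo)) "inactive" else sprintf("[%g, %g] %s", lo, hi, unit)
  }
  cat("<filter_params>\n")
  cat("  area:        ", fmt(x$area_min_um2, x$area_max_um2, "um^2"), "\n")
  cat("  circularity: ", fmt(x$circ_min, x$circ_max, ""), "\n")
  cat("  perimeter:   ", fmt(x$perim_min_um, x$perim_max_um, "um"), "\n")
  invisible(x)
}

#' Apply inclusion filters to detections
#'
#' Keeps exactly the detections inside every active closed interval of
#' `params`; row order is preserved and the input is not modified. Filtering
#' is idempotent and its output is always a subset of its input.
#'
#' @param detections Tibble from [measure_particles()] (columns `area_um2`,
#'   `circularity`, `perimeter_um`).
#' @param params A [filter_params()] object.
#'
#' @return The retained rows of `detections`.
#' @export
filter_particles <- function(detections, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  keep <- rep(TRUE, nrow(detections))
  if (!is.null(params$area_min_um2)) {
    keep <- keep & detections$area_um2 >= params$area_min_um2 &
      detections$area_um2 <= params$area_max_um2
  }
  if (!is.null(params$circ_min)) {
    keep <- keep & detections$circularity >= params$circ_min &
      detections$circularity <= params$circ_max
  }
  if (!is.null(params$perim_min_um)) {
    keep <- keep & detections$perimeter_um >= params$perim_min_um &
      detections$perimeter_um <= params$perim_max_um
  }
  detections[keep, , drop = FALSE]
}
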