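#' Match detections to ground-truth cells
#'
#' Greedy one-to-one nearest-neighbour matching between ground-truth cells
#' (artefacts excluded) and detections. A truth-detection pair is a candidate
#' when the centroid distance is within the truth cell's equivalent radius
#' `sqrt(true_area_px / pi)`; candidates are assigned closest-first.
#'
#' @param detections Detection tibble ([segment_edge()] and friends).
#' @param truth Truth tibble from [generate_tissue()].
#' @param microns_per_pixel Pixel size used to convert truth areas to pixels.
#'
#' @return A tibble with one row per matched pair: `cell_id`, `label`,
#'   `dist_px`, `true_area_um2`, `det_area_um2`, `rel_area_error`
#'   (signed, `(det - true) / true`).
#' @export
match_truth <- function(detections, truth, microns_per_pixel) {
  cells <- truth[!truth$is_artifact, , drop = FALSE]
  empty <- tibble(
    cell_id = integer(), label = integer(), dist_px = double(),
    true_area_um2 = double(), det_area_um2 = double(), rel_area_error = double()
  )
  if (nrow(cells) == 0 || nrow(detections) == 0) return(empty)

  radius <- sqrt((cells$true_area_um2 / microns_per_pixel^2) / pi)
  dx <- outer(cells$centroid_x_px, detections$centroid_x_px, "-")
  dy <- outer(cells$centroid_y_px, detections$centroid_y_px, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(d[cand]), , drop = FALSE]

  used_t <- logical(nrow(cells))
  used_d <- logical(nrow(detections))
  ti <- integer(0)
  di <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]
    j <- cand[k, 2]
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- TRUE
      used_d[j] <- TRUE
      ti <- c(ti, i)
      di <- c(di, j)
    }
  }
  tibble(
    cell_id = cells$cell_id[ti],
    label = detections$label[di],
    dist_px = d[cbind(ti, di)],
    true_area_um2 = cells$true_area_um2[ti],
    det_area_um2 = detections$area_um2[di],
    rel_area_error = (detections$area_um2[di] - cells$true_area_um2[ti]) /
      cells$true_area_um2[ti]
  )
}

#' Recall, precision and area accuracy against ground truth
#'
#' Scores a detection set against a slide's truth table via [match_truth()]:
#' recall is the fraction of (non-artefact) truth cells matched, precision the
#' fraction of detections matched, and the area error summary is the median
#' absolute relative area error over matched pairs.
#'
#' @inheritParams match_truth
#'
#' @return A one-row tibble: `n_truth`, `n_detections`, `n_matched`,
#'   `recall`, `precision`, `median_abs_rel_area_error`.
#' @export
score_detections <- function(detections, truth, microns_per_pixel) {
  m <- match_truth(detections, truth, microns_per_pixel)
  n_truth <- sum(!truth$is_artifact)
  n_det <- nrow(detections)
  tibble(
    n_truth = n_truth,
    n_detections = n_det,
    n_matched = nrow(m),
    recall = if (n_truth > 0) nrow(m) / n_truth else NA_real_,
    precision = if (n_det > 0) nrow(m) / n_det else NA_real_,
    median_abs_rel_area_error =
      if (nrow(m) > 0) stats::median(abs(m$rel_area_error)) else NA_real_
  )
}
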