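#' Specification of a synthetic H&E-like adipose slide
#'
#' Parameters of the ground-truth tissue generator. White adipocytes are
#' emulated as a confluent, multiplicatively weighted Voronoi tessellation of
#' bright lumina separated by thin dark membranes, surrounded by near-white
#' background, with optional non-adipocyte artefacts. Cell areas follow a
#' log-normal law (adipocyte size histograms are strongly right-skewed).
#' Intensity ranges are constrained so that the 230/231 membrane/fat boundary
#' used by the threshold pipeline stays meaningful: membranes never exceed
#' 230, lumina never fall below 231, background is whitespace at 245 or above.
#'
#' @param n_cells Target number of adipocytes.
#' @param mu_log,sigma_log Log-normal parameters of the cell area distribution
#'   in log square-micrometres (median area = `exp(mu_log)`).
#' @param microns_per_pixel Pixel size in micrometres (default 1).
#' @param width_px,height_px Image size; `NULL` (default) sizes the frame so
#'   the sampled cells tile the tissue block at confluence.
#' @param margin_px Background margin around the tissue block (default 40 px);
#'   artefacts are placed in this margin so they never disturb the cells.
#' @param membrane_px Membrane thickness in pixels (odd, default 3).
#' @param membrane_intensity Length-2 intensity range for membranes (max 230).
#' @param lumen_intensity Length-2 intensity range for lumen fill (min 231).
#' @param background_intensity Whitespace intensity (at least 245).
#' @param n_crushed,n_vessels,n_specks Artefact counts: crushed regions
#'   (elongated bright regions with circularity below 0.3), vessels (filled
#'   dark structures), and sub-minimum bright specks (below 500 um^2).
#' @param noise_sd Gaussian intensity noise standard deviation (default 4).
#'   After noise, membrane and lumen pixels are clamped back to their side of
#'   the 230/231 boundary and background to 245+, so the generated classes
#'   remain exact.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#'
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(n_cells = 300,
                        mu_log = log(2100), sigma_log = 0.35,
                        microns_per_pixel = 0.5,
                        width_px = NULL, height_px = NULL,
                        margin_px = 40,
                        membrane_px = 5,
                        membrane_intensity = c(90, 150),
                        lumen_intensity = c(235, 244),
                        background_intensity = 250,
                        n_crushed = 0, n_vessels = 0, n_specks = 0,
                        noise_sd = 4,
                        seed = 1) {
  if (n_cells < 0) abort("`n_cells` must be >= 0.")
  if (sigma_log < 0) abort("`sigma_log` must be >= 0.")
  if (microns_per_pixel <= 0) abort("`microns_per_pixel` must be positive.")
  if (membrane_px < 1 || membrane_px %% 2 != 1) {
    abort("`membrane_px` must be an odd positive integer.")
  }
  if (max(membrane_intensity) > 230 || min(membrane_intensity) < 0) {
    abort("`membrane_intensity` must lie within [0, 230].")
  }
  if (min(lumen_intensity) < 231 || max(lumen_intensity) > 255) {
    abort("`lumen_intensity` must lie within [231, 255].")
  }
  if (background_intensity < 245 || background_intensity > 255) {
    abort("`background_intensity` must lie within [245, 255].")
  }
  if ((n_crushed > 0 || n_vessels > 0 || n_specks > 0) && margin_px < 36) {
    abort("Artefacts are placed in the background margin; use `margin_px` >= 36.")
  }
  structure(
    list(
      n_cells = as.integer(n_cells),
      mu_log = mu_log, sigma_log = sigma_log,
      microns_per_pixel = microns_per_pixel,
      width_px = width_px, height_px = height_px,
      margin_px = as.integer(margin_px),
      membrane_px = as.integer(membrane_px),
      membrane_intensity = as.integer(membrane_intensity),
      lumen_intensity = as.integer(lumen_intensity),
      background_intensity = as.integer(background_intensity),
      n_crushed = as.integer(n_crushed),
      n_vessels = as.integer(n_vessels),
      n_specks = as.integer(n_specks),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "tissue_spec"
  )
}

#' Chow-like and HFD-like default slide specifications
#'
#' Study-condition presets for [make_cohort()]. The chow preset targets a
#' median adipocyte area of 2,100 um^2 (sigma_log 0.35) and the high-fat-diet
#' preset 3,150 um^2 (sigma_log 0.45), placing the group means near the
#' published whole-slide ranges for control and high-fat-diet mice and
#' shifting HFD area mass above 5,000 um^2.
#'
#' The HFD preset also carries 1.5x more cells per slide (450 vs 300):
#' high-fat feeding roughly doubles depot mass, so HFD sections expose more
#' adipocytes to whole-slide analysis even as each single field of view holds
#' fewer of the enlarged cells.
#'
#' @param n_cells Cells per slide (default 300 chow-like, 450 HFD-like).
#' @param ... Further arguments passed to [tissue_spec()].
#' @return A [tissue_spec()].
#' @export
default_chow_spec <- function(n_cells = 300, ...) {
  tissue_spec(n_cells = n_cells, mu_log = log(2100), sigma_log = 0.35, ...)
}

#' @rdname default_chow_spec
#' @export
default_hfd_spec <- function(n_cells = 450, ...) {
  tissue_spec(n_cells = n_cells, mu_log = log(3150), sigma_log = 0.45, ...)
}

# Dart-throwing placement of cell centres inside the inner tissue rectangle.
# rho: territory radii (px), placed largest-first. The spacing requirement
# starts at 0.85 * (rho_i + rho_j) and is relaxed stepwise for a cell that
# cannot be seated, so confluent (100% tiling) densities always place; the
# subsequent centroid relaxation evens out any locally crowded seeds.
# Returns cbind(y, x) in the original cell order or NULL when even overlapping
# placement is geometrically impossible.
.place_centers <- function(rho, inner, attempts_per_level = 150L) {
  n <- length(rho)
  ord <- order(rho, decreasing = TRUE)
  ys <- numeric(n)
  xs <- numeric(n)
  placed_r <- numeric(0)
  for (k in seq_len(n)) {
    i <- ord[k]
    r <- rho[i]
    lo_y <- inner$y0 + 0.6 * r
    hi_y <- inner$y1 - 0.6 * r
    lo_x <- inner$x0 + 0.6 * r
    hi_x <- inner$x1 - 0.6 * r
    if (lo_y >= hi_y || lo_x >= hi_x) return(NULL)
    ok <- FALSE
    for (spacing in c(0.85, 0.75, 0.65, 0.5, 0.35, 0.2)) {
      for (a in seq_len(attempts_per_level)) {
        cy <- runif(1, lo_y, hi_y)
        cx <- runif(1, lo_x, hi_x)
        if (k == 1L) { ok <- TRUE } else {
          prev <- seq_len(k - 1L)
          d2 <- (ys[ord[prev]] - cy)^2 + (xs[ord[prev]] - cx)^2
          ok <- all(d2 >= (spacing * (placed_r + r))^2)
        }
        if (ok) break
      }
      if (ok) break
    }
    if (!ok) return(NULL)
    ys[i] <- cy
    xs[i] <- cx
    placed_r <- c(placed_r, r)
  }
  cbind(y = ys, x = xs)
}

# Lloyd-style relaxation of the weighted tessellation: move each centre to its
# territory centroid and re-tessellate. Evens out crowded seeds so cell areas
# track their log-normal targets.
.relax_centers <- function(centers, rho, H, W, inner, sweeps = 2L) {
  for (s in seq_len(sweeps)) {
    L <- .nearest_center(H, W, centers[, "y"], centers[, "x"], rho,
                         inner$y0, inner$y1, inner$x0, inner$x1)
    fg <- which(L > 0L)
    lab <- L[fg]
    ai <- arrayInd(fg, dim(L))
    cnt <- tabulate(lab, nbins = nrow(centers))
    sums <- rowsum(cbind(ai[, 1], ai[, 2]), group = lab)
    ids <- as.integer(rownames(sums))
    centers[ids, "y"] <- pmin(pmax(sums[, 1] / cnt[ids], inner$y0), inner$y1)
    centers[ids, "x"] <- pmin(pmax(sums[, 2] / cnt[ids], inner$x0), inner$x1)
  }
  centers
}

# Paint a filled axis-aligned rectangle, returning the linear indices.
.rect_idx <- function(nr, y0, y1, x0, x1) {
  yy <- rep(y0:y1, times = x1 - x0 + 1L)
  xx <- rep(x0:x1, each = y1 - y0 + 1L)
  (xx - 1L) * nr + yy
}

.disc_idx <- function(nr, nc, cy, cx, r) {
  y0 <- max(1L, floor(cy - r)); y1 <- min(nr, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(nc, ceiling(cx + r))
  yy <- rep(y0:y1, times = x1 - x0 + 1L)
  xx <- rep(x0:x1, each = y1 - y0 + 1L)
  keep <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  (xx[keep] - 1L) * nr + yy[keep]
}

#' Generate a synthetic adipose slide with ground truth
#'
#' Builds one calibrated H&E-like image and its per-cell truth table. Cell
#' centres are dart-thrown at sizes drawn from the spec's log-normal law, a
#' weighted Voronoi tessellation tiles the tissue block, each cell is shrunk
#' by the membrane thickness to create its lumen, and intensities are painted
#' with Gaussian noise. Truth areas, perimeters, circularities and centroids
#' are measured from the pre-noise lumen label image with the same
#' crack-boundary conventions as [measure_particles()], so truth and
#' detections are directly commensurable. Artefacts are placed in the
#' background margin so they never alter the adipocytes.
#'
#' @param spec A [tissue_spec()].
#'
#' @return A list of class `synthetic_slide` with elements `image` (a
#'   [calibrated_image()]), `truth` (tibble: `cell_id`, `true_area_um2`,
#'   `true_perimeter_um`, `true_circularity`, `centroid_x_px`,
#'   `centroid_y_px`, `is_artifact`, `artifact_kind`), and `spec`.
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  withr::with_seed(spec$seed, .generate_tissue_impl(spec))
}

.generate_tissue_impl <- function(spec) {
  mpp <- spec$microns_per_pixel
  mt <- spec$membrane_px
  margin <- spec$margin_px
  n <- spec$n_cells

  truth_empty <- tibble(
    cell_id = integer(), true_area_um2 = double(), true_perimeter_um = double(),
    true_circularity = double(), centroid_x_px = double(), centroid_y_px = double(),
    is_artifact = logical(), artifact_kind = character()
  )

  if (n == 0L) {
    W <- if (is.null(spec$width_px)) 2L * margin + 64L else as.integer(spec$width_px)
    H <- if (is.null(spec$height_px)) 2L * margin + 64L else as.integer(spec$height_px)
    img <- matrix(spec$background_intensity, H, W)
    img <- .apply_noise(img, spec, dark = integer(), bright = integer())
    return(structure(
      list(image = calibrated_image(img, mpp), truth = truth_empty, spec = spec),
      class = "synthetic_slide"
    ))
  }

  # target areas and territory radii (lumen radius + half membrane)
  a_um2 <- exp(rnorm(n, spec$mu_log, spec$sigma_log))
  a_px <- a_um2 / mpp^2
  rho <- sqrt(a_px / pi) + mt / 2

  if (is.null(spec$width_px)) {
    inner_side <- ceiling(sqrt(sum(pi * rho^2)))
    W <- H <- as.integer(inner_side + 2L * margin)
  } else {
    W <- as.integer(spec$width_px)
    H <- as.integer(spec$height_px %||% spec$width_px)
    inner_area <- (W - 2L * margin) * (H - 2L * margin)
    if (inner_area <= 0 || sum(pi * rho^2) > 1.1 * inner_area) {
      abort("Infeasible packing: the sampled cells do not fit the tissue block; enlarge the image or reduce `n_cells`.")
    }
  }
  inner <- list(y0 = margin + 1L, y1 = H - margin, x0 = margin + 1L, x1 = W - margin)

  centers <- .place_centers(rho, inner)
  if (is.null(centers)) {
    abort("Infeasible packing: could not place all cell centres; enlarge the image or reduce `n_cells`.")
  }
  centers <- .relax_centers(centers, rho, H, W, inner)

  L <- .nearest_center(H, W, centers[, "y"], centers[, "x"], rho,
                       inner$y0, inner$y1, inner$x0, inner$x1)

  # one-sided crack between differing labels (incl. tissue edge), thickened to
  # the membrane width
  zr <- matrix(0L, H, 1L)
  zc <- matrix(0L, 1L, W)
  right <- cbind(L[, -1, drop = FALSE], zr)
  down <- rbind(L[-1, , drop = FALSE], zc)
  crack <- (L != right & (L > 0L | right > 0L)) | (L != down & (L > 0L | down > 0L))
  membrane <- .dilate_mask(crack, mt)

  lumen <- L
  lumen[membrane] <- 0L
  truth_cells <- measure_label_matrix(lumen, mpp)
  truth_cells <- tibble(
    cell_id = truth_cells$label,
    true_area_um2 = truth_cells$area_um2,
    true_perimeter_um = truth_cells$perimeter_um,
    true_circularity = truth_cells$circularity,
    centroid_x_px = truth_cells$centroid_x_px,
    centroid_y_px = truth_cells$centroid_y_px,
    is_artifact = FALSE,
    artifact_kind = NA_character_
  )

  # paint
  img <- matrix(spec$background_intensity * 1.0, H, W)
  mem_idx <- which(membrane & (L > 0L | .dilate_mask(L > 0L, mt)))
  img[mem_idx] <- sample(spec$membrane_intensity[1]:spec$membrane_intensity[2],
                         length(mem_idx), replace = TRUE)
  lum_idx <- which(lumen > 0L)
  cell_base <- sample(spec$lumen_intensity[1]:spec$lumen_intensity[2], n, replace = TRUE)
  img[lum_idx] <- cell_base[lumen[lum_idx]]

  art <- .place_artifacts(img, spec, H, W)
  img <- art$img
  truth <- dplyr::bind_rows(truth_cells, art$truth)

  img <- .apply_noise(img, spec,
                      dark = c(mem_idx, art$dark_idx),
                      bright = c(lum_idx, art$bright_idx))

  structure(
    list(image = calibrated_image(img, mpp), truth = truth, spec = spec),
    class = "synthetic_slide"
  )
}

# Gaussian noise, clipping, and re-assertion of the class intensity bands.
.apply_noise <- function(img, spec, dark, bright) {
  if (spec$noise_sd > 0) {
    img <- img + round(rnorm(length(img), 0, spec$noise_sd))
  }
  img <- pmin(pmax(img, 0), 255)
  if (length(dark)) img[dark] <- pmin(img[dark], 230)
  if (length(bright)) img[bright] <- pmax(img[bright], 231)
  bg <- setdiff(seq_along(img), c(dark, bright))
  img[bg] <- pmax(img[bg], 245)
  img
}

# Artefacts live in the top/bottom background margins: crushed regions are
# long bright bars ringed by membrane (in the area window but circularity
# < 0.3), vessels are filled dark discs, specks are bright dots below the
# 500 um^2 floor. Truth rows are measured with the shared conventions.
.place_artifacts <- function(img, spec, H, W) {
  truth <- NULL
  dark_idx <- integer()
  bright_idx <- integer()
  alab <- matrix(0L, H, W)
  akind <- character()
  next_id <- 0L
  margin <- spec$margin_px
  mpp <- spec$microns_per_pixel
  cursor_x <- 8L

  mem_draw <- function(k) {
    sample(spec$membrane_intensity[1]:spec$membrane_intensity[2], k, replace = TRUE)
  }
  lum_draw <- function(k) {
    sample(spec$lumen_intensity[1]:spec$lumen_intensity[2], k, replace = TRUE)
  }
  take_slot <- function(w) {
    if (cursor_x + w + 8L > W) abort("Margin too small for the requested artefacts.")
    x0 <- cursor_x
    cursor_x <<- cursor_x + w + 12L
    x0
  }

  # artefact dimensions are physical so behaviour is stable across resolutions
  rod_len <- min(as.integer(round(150 / mpp)), W - 30L)
  rod_h <- max(4L, as.integer(round(6 / mpp)))
  for (i in seq_len(spec$n_crushed)) {
    w <- rod_len
    h <- rod_h
    x0 <- take_slot(w)
    y0 <- max(4L, (margin - h) %/% 2)
    ring <- .rect_idx(H, y0 - 3L, y0 + h + 2L, x0 - 3L, x0 + w + 2L)
    core <- .rect_idx(H, y0, y0 + h - 1L, x0, x0 + w - 1L)
    ring <- setdiff(ring, core)
    img[ring] <- mem_draw(length(ring))
    img[core] <- lum_draw(length(core))
    dark_idx <- c(dark_idx, ring)
    bright_idx <- c(bright_idx, core)
    next_id <- next_id + 1L
    alab[core] <- next_id
    akind <- c(akind, "crushed")
  }
  for (i in seq_len(spec$n_vessels)) {
    r <- min(max(6L, as.integer(round(15 / mpp))), margin %/% 2L - 2L)
    x0 <- take_slot(2L * r + 2L)
    core <- .disc_idx(H, W, margin %/% 2, x0 + r, r)
    img[core] <- mem_draw(length(core))
    dark_idx <- c(dark_idx, core)
    next_id <- next_id + 1L
    alab[core] <- next_id
    akind <- c(akind, "vessel")
  }
  for (i in seq_len(spec$n_specks)) {
    r <- max(2L, floor(sqrt(450 / mpp^2 / pi) / 2))
    x0 <- take_slot(2L * r + 8L)
    cy <- H - margin %/% 2
    ring <- .disc_idx(H, W, cy, x0 + r, r + 3L)
    core <- .disc_idx(H, W, cy, x0 + r, r)
    ring <- setdiff(ring, core)
    img[ring] <- mem_draw(length(ring))
    img[core] <- lum_draw(length(core))
    dark_idx <- c(dark_idx, ring)
    bright_idx <- c(bright_idx, core)
    next_id <- next_id + 1L
    alab[core] <- next_id
    akind <- c(akind, "speck")
  }

  if (next_id > 0L) {
    m <- measure_label_matrix(alab, mpp)
    truth <- tibble(
      cell_id = -m$label,
      true_area_um2 = m$area_um2,
      true_perimeter_um = m$perimeter_um,
      true_circularity = m$circularity,
      centroid_x_px = m$centroid_x_px,
      centroid_y_px = m$centroid_y_px,
      is_artifact = TRUE,
      artifact_kind = akind[m$label]
    )
  }
  list(img = img, truth = truth, dark_idx = dark_idx, bright_idx = bright_idx)
}

#' @export
print.synthetic_slide <- function(x, ...) {
  d <- dim(x$image$pixels)
  cat(sprintf(
    "<synthetic_slide> %d x %d px, %d truth cells (%d artefacts), seed %d\n",
    d[2], d[1], sum(!x$truth$is_artifact), sum(x$truth$is_artifact), x$spec$seed
  ))
  invisible(x)
}

#' Simulate a two-group cohort of synthetic slides
#'
#' Generates `n_slides_per_group` slides per diet group from a chow-like and
#' an HFD-like [tissue_spec()], with per-slide seeds `base_seed + index` so
#' the whole cohort is reproducible from one integer. Optionally writes
#' LZW-compressed TIFFs plus `truth.csv` and `manifest.csv` to `out_dir`.
#'
#' @param chow_spec,hfd_spec [tissue_spec()] objects for the two groups.
#' @param n_slides_per_group Slides per group (default 3).
#' @param base_seed Base integer seed.
#' @param out_dir Optional output directory for TIFFs and CSVs.
#'
#' @return A list of class `adipo_cohort`: `slides` (named list of
#'   `synthetic_slide`), `manifest` (tibble: `slide_id`, `group`, `seed`,
#'   `image_path`), `truth` (combined truth tibble with `slide_id`).
#' @export
make_cohort <- function(chow_spec = default_chow_spec(),
                        hfd_spec = default_hfd_spec(),
                        n_slides_per_group = 3,
                        base_seed = 1,
                        out_dir = NULL) {
  groups <- rep(c("chow", "hfd"), each = n_slides_per_group)
  specs <- rep(list(chow_spec, hfd_spec), each = n_slides_per_group)
  idx <- seq_along(groups)
  ids <- sprintf("%s_%02d", groups, rep(seq_len(n_slides_per_group), 2))

  slides <- purrr::map(idx, function(i) {
    sp <- specs[[i]]
    sp$seed <- as.integer(base_seed + i)
    generate_tissue(sp)
  })
  names(slides) <- ids

  paths <- rep(NA_character_, length(ids))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, paste0(ids, ".tif"))
    purrr::walk2(slides, paths, function(s, p) write_calibrated_image(s$image, p))
  }

  manifest <- tibble(
    slide_id = ids, group = groups,
    seed = as.integer(base_seed + idx),
    image_path = paths
  )
  truth <- purrr::map2_dfr(slides, ids, function(s, id) {
    dplyr::bind_cols(tibble(slide_id = rep(id, nrow(s$truth))), s$truth)
  })
  if (!is.null(out_dir)) {
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  structure(
    list(slides = slides, manifest = manifest, truth = truth),
    class = "adipo_cohort"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
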