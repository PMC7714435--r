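# Independent brute-force flood-fill labelling oracle (BFS), renumbered in
# raster-scan (row-major) order of first pixel — used to cross-check the
# package's union-find labelling.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    moves <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  nxt <- 0L
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      if (mask[y, x] == 0 || lab[y, x] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(y, x))
      lab[y, x] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (m in seq_len(nrow(moves))) {
          yy <- p[1] + moves[m, 1]
          xx <- p[2] + moves[m, 2]
          if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc &&
              mask[yy, xx] != 0 && lab[yy, xx] == 0L) {
            lab[yy, xx] <- nxt
            queue <- c(queue, list(c(yy, xx)))
          }
        }
      }
    }
  }
  attr(lab, "n_labels") <- nxt
  lab
}

# Filled digital disk mask.
disk_mask <- function(nr, nc, cy, cx, r) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Grid of bright lumina (disks) on a dark membrane background: the idealised
# tissue image used to exercise the pipelines with known geometry.
disk_grid_image <- function(n_side = 3, r = 26, gap = 14,
                            lumen = 240, membrane = 120,
                            microns_per_pixel = 1) {
  pitch <- 2 * r + gap
  side <- n_side * pitch + gap
  px <- matrix(membrane, side, side)
  centers <- list()
  for (i in seq_len(n_side)) {
    for (j in seq_len(n_side)) {
      cy <- gap + r + (i - 1) * pitch
      cx <- gap + r + (j - 1) * pitch
      px[disk_mask(side, side, cy, cx, r)] <- lumen
      centers[[length(centers) + 1]] <- c(cy, cx)
    }
  }
  list(
    image = calibrated_image(px, microns_per_pixel),
    centers = do.call(rbind, centers),
    r = r,
    disk_px = sum(disk_mask(side, side, gap + r, gap + r, r))
  )
}

# Small, fast synthetic slide for unit tests (coarser than the study-default
# spec on purpose: unit tests check properties, not study conditions).
small_slide_spec <- function(n_cells = 40, seed = 1, ...) {
  tissue_spec(
    n_cells = n_cells, microns_per_pixel = 1, membrane_px = 3,
    mu_log = log(2000), sigma_log = 0.25, seed = seed, ...
  )
}
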