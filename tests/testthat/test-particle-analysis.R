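test_that("component labelling handles the canonical toy cases", {
  expect_equal(n_labels(label_components(matrix(0L, 5, 5))), 0L)

  m <- matrix(0L, 5, 5)
  m[1:2, 1:2] <- 1L
  m[3:4, 3:4] <- 1L
  expect_equal(n_labels(label_components(m, 4)), 2L)
  expect_equal(n_labels(label_components(m, 8)), 1L)

  b <- matrix(0L, 5, 5)
  b[2:4, 2:4] <- 1L
  lab <- label_components(b)
  expect_equal(n_labels(lab), 1L)
  expect_equal(sum(lab == 1L), 9L)

  expect_error(label_components(matrix(2L, 2, 2)), "binary")
})

test_that("labelling matches a brute-force flood fill on random grids", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rbinom(256, 1, 0.45), 16, 16)
    for (conn in c(4, 8)) {
      got <- label_components(m, conn)
      want <- flood_fill_label(m, conn)
      expect_identical(unclass(got)[, ], want[, ])
      expect_equal(n_labels(got), attr(want, "n_labels"))
    }
  }
})

test_that("per-label pixel counts conserve the foreground total", {
  set.seed(7)
  m <- matrix(rbinom(900, 1, 0.4), 30, 30)
  lab <- label_components(m, 8)
  expect_equal(sum(tabulate(lab[lab > 0], n_labels(lab))), sum(m))
})

test_that("measurement reproduces closed-form square and pixel geometry", {
  m <- matrix(0L, 12, 12)
  m[2:11, 2:11] <- 1L
  det <- measure_particles(label_components(m), 1)
  expect_equal(det$area_um2, 100)
  expect_equal(det$perimeter_um, 40)
  expect_equal(det$circularity, pi / 4)
  expect_equal(det$centroid_x_px, 6.5)
  expect_equal(det$centroid_y_px, 6.5)

  det2 <- measure_particles(label_components(m), 2)
  expect_equal(det2$area_um2, 400)
  expect_equal(det2$perimeter_um, 80)
  expect_equal(det2$circularity, pi / 4)

  one <- matrix(0L, 3, 3)
  one[2, 2] <- 1L
  d1 <- measure_particles(label_components(one), 1)
  expect_equal(d1$area_um2, 1)
  expect_equal(d1$perimeter_um, 4)
  expect_equal(d1$circularity, pi / 4)
})

test_that("area scales as scale^2, perimeter as scale, circularity not at all", {
  set.seed(3)
  m <- matrix(rbinom(400, 1, 0.5), 20, 20)
  lab <- label_components(m, 8)
  base <- measure_particles(lab, 1)
  for (s in c(0.25, 0.5, 1, 2)) {
    det <- measure_particles(lab, s)
    expect_equal(det$area_um2, base$area_um2 * s^2)
    expect_equal(det$perimeter_um, base$perimeter_um * s)
    expect_equal(det$circularity, base$circularity)
  }
})

test_that("digitised disk circularity converges to pi^2/16 under the crack convention", {
  # the crack boundary of a convex digital set is its staircase length
  # 2*(width + height) = 8r for a disk, so circularity tends to
  # 4*pi*(pi r^2) / (8r)^2 = pi^2/16 ~ 0.617 -- well above the 0.3 crushed-
  # artefact floor and well below rod-like artefacts' ~0.1
  for (r in c(10, 20, 30, 40, 50)) {
    side <- 2 * r + 5
    m <- disk_mask(side, side, r + 3, r + 3, r)
    det <- measure_particles(label_components(m), 1)
    expect_gte(det$circularity, 0.55)
    expect_lte(det$circularity, 0.68)
  }
  big <- disk_mask(205, 205, 103, 103, 100)
  det <- measure_particles(label_components(big), 1)
  expect_equal(det$circularity, pi^2 / 16, tolerance = 0.02)
})

test_that("inclusion filters use closed intervals and behave as set operations", {
  det <- tibble::tibble(
    label = 1:6,
    area_um2 = c(499, 500, 20000, 20001, 1000, 1000),
    perimeter_um = c(100, 100, 500, 500, 900, 901),
    circularity = c(0.5, 0.30, 1.0, 0.5, 0.29, 0.9),
    centroid_x_px = 0, centroid_y_px = 0
  )
  p_area <- filter_params()
  expect_equal(filter_particles(det, p_area)$label, c(2L, 3L, 5L, 6L))

  p_circ <- filter_params(circ_min = 0.3, circ_max = 1.0)
  expect_equal(filter_particles(det, p_circ)$label, c(2L, 3L, 6L))

  p_per <- filter_params(perim_min_um = 0, perim_max_um = 900)
  expect_equal(filter_particles(det, p_per)$label, c(2L, 3L, 5L))

  # idempotent, subset, order-preserving, input untouched
  once <- filter_particles(det, p_circ)
  expect_identical(filter_particles(once, p_circ), once)
  expect_true(all(once$label %in% det$label))
  expect_equal(nrow(det), 6L)
  expect_equal(nrow(filter_particles(det[0, ], p_area)), 0L)

  expect_error(filter_params(area_min_um2 = 10, area_max_um2 = 5), "smaller")
  expect_error(filter_params(circ_min = 0.5, circ_max = 1.2), "circ")
})
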