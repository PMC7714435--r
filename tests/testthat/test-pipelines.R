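test_that("membrane/fat classification splits exactly at 230/231", {
  expect_equal(classify_membrane_fat(c(0, 120, 230)), rep("membrane", 3))
  expect_equal(classify_membrane_fat(c(231, 240, 255)), rep("fat", 3))
})

test_that("tissue detection distinguishes whitespace, tissue and enclosed lumina", {
  blank <- calibrated_image(matrix(255L, 40, 40), 1)
  expect_false(any(detect_tissue(blank)))

  solid <- calibrated_image(matrix(100L, 40, 40), 1)
  expect_true(all(detect_tissue(solid, tissue_params(min_tissue_fragment_um2 = 0))))

  # dark disk on white background -> mask is (a closed superset of) the disk
  side <- 80
  dm <- disk_mask(side, side, 40, 40, 20)
  px <- matrix(255L, side, side)
  px[dm] <- 100L
  got <- detect_tissue(
    calibrated_image(px, 1),
    tissue_params(min_tissue_fragment_um2 = 0, closing_radius_px = 2)
  )
  expect_true(all(got[dm]))
  expect_lte(sum(got & !dm) / sum(dm), 0.05)

  # a bright lumen enclosed in the disk is retained as tissue via hole filling
  hole <- disk_mask(side, side, 40, 40, 6)
  px2 <- px
  px2[hole] <- 250L
  got2 <- detect_tissue(
    calibrated_image(px2, 1),
    tissue_params(min_tissue_fragment_um2 = 0, closing_radius_px = 2)
  )
  expect_true(all(got2[hole]))
})

test_that("edge pipeline recovers disk lumina and respects the area floor", {
  g <- disk_grid_image(n_side = 3, r = 26)
  det <- segment_edge(g$image)
  expect_equal(nrow(det), 9L)
  # iterated edge bands erode each lumen by a few pixels but never inflate it
  expect_true(all(det$area_um2 <= g$disk_px))
  expect_true(all(det$area_um2 >= pi * (g$r - 5)^2))
  # detected centroids sit on the constructed disk centres
  ord <- order(det$centroid_y_px, det$centroid_x_px)
  cen <- g$centers[order(g$centers[, 1], g$centers[, 2]), ]
  expect_lt(max(abs(det$centroid_y_px[ord] - cen[, 1])), 1.5)
  expect_lt(max(abs(det$centroid_x_px[ord] - cen[, 2])), 1.5)

  # gradient-free image -> no detections, with a warning
  flat <- calibrated_image(matrix(200L, 60, 60), 1)
  expect_warning(d0 <- segment_edge(flat), "gradient")
  expect_equal(nrow(d0), 0L)

  # a disk below the 500 um^2 floor is filtered out
  small <- disk_grid_image(n_side = 1, r = 9)  # ~254 um^2
  expect_equal(nrow(segment_edge(small$image)), 0L)
})

test_that("threshold pipeline detects exactly the fat regions", {
  g <- disk_grid_image(n_side = 2, r = 26, lumen = 240, membrane = 120)
  det <- segment_threshold(g$image)
  expect_equal(nrow(det), 4L)
  expect_equal(det$area_um2, rep(g$disk_px, 4))

  # classification boundary: 230 is membrane, 231 is fat
  px <- matrix(230L, 60, 60)
  px[disk_mask(60, 60, 30, 30, 20)] <- 231L
  det231 <- segment_threshold(calibrated_image(px, 1))
  expect_equal(nrow(det231), 1L)
  px[px == 231L] <- 230L
  expect_equal(nrow(segment_threshold(calibrated_image(px, 1))), 0L)
})

test_that("hole filling counts enclosed membrane specks into the fat object", {
  px <- matrix(120L, 60, 60)
  sq <- matrix(FALSE, 60, 60)
  sq[16:45, 16:45] <- TRUE        # 30 x 30 fat block = 900 px
  px[sq] <- 240L
  px[30, 30] <- 100L              # 1-px membrane speck inside
  img <- calibrated_image(px, 1)
  with_fill <- segment_threshold(img)
  without_fill <- segment_threshold(img, threshold_params(fill_holes = FALSE))
  expect_equal(with_fill$area_um2, 900)
  expect_equal(without_fill$area_um2, 899)
})

test_that("micrograph percentile threshold follows the cumulative-fraction rule", {
  # two-level image: 50% at 50, 50% at 200 -> threshold 50, lumina = the 200s
  px <- matrix(50L, 40, 40)
  px[, 21:40] <- 200L
  det <- segment_micrograph(
    calibrated_image(px, 1),
    micrograph_params(percentile = 0.5, n_dilates = 0,
                      filters = filter_params(area_min_um2 = 1, area_max_um2 = 1e7))
  )
  expect_equal(sum(det$area_um2), sum(px == 200L))

  flat <- calibrated_image(matrix(77L, 30, 30), 1)
  expect_warning(d0 <- segment_micrograph(flat), "[Dd]egenerate")
  expect_equal(nrow(d0), 0L)
})

test_that("micrograph dilation shrinks lumina, biasing areas low but keeping counts", {
  g <- disk_grid_image(n_side = 2, r = 30, gap = 16)
  det <- segment_micrograph(g$image, micrograph_params(percentile = 0.3, n_dilates = 5))
  expect_equal(nrow(det), 4L)
  expect_true(all(det$area_um2 < g$disk_px))
})

test_that("an empty tissue mask yields a warning and no detections", {
  g <- disk_grid_image(n_side = 2, r = 26)
  none <- matrix(FALSE, nrow(g$image$pixels), ncol(g$image$pixels))
  expect_warning(d <- segment_threshold(g$image, tissue = none), "empty")
  expect_equal(nrow(d), 0L)
  expect_warning(d2 <- segment_edge(g$image, tissue = none), "empty")
  expect_equal(nrow(d2), 0L)
})

test_that("identical inputs give byte-identical detection CSVs", {
  s <- generate_tissue(small_slide_spec(n_cells = 20, seed = 5))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  readr::write_csv(segment_threshold(s$image), f1)
  readr::write_csv(segment_threshold(s$image), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})
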