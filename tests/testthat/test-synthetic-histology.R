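test_that("the generator is deterministic given the spec seed", {
  sp <- small_slide_spec(n_cells = 25, seed = 9)
  a <- generate_tissue(sp)
  b <- generate_tissue(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("an empty spec yields pure whitespace and an empty truth table", {
  s <- generate_tissue(tissue_spec(n_cells = 0, seed = 2))
  expect_equal(nrow(s$truth), 0L)
  expect_true(all(s$image$pixels >= 245))
})

test_that("equal-area specs produce cells near the target size", {
  sp <- tissue_spec(n_cells = 40, mu_log = log(2000), sigma_log = 0,
                    microns_per_pixel = 1, membrane_px = 3, seed = 4)
  s <- generate_tissue(sp)
  tr <- s$truth
  expect_equal(nrow(tr), 40L)
  expect_lt(abs(mean(tr$true_area_um2) - 2000) / 2000, 0.15)
  expect_true(all(tr$true_area_um2 > 0.4 * 2000))
  expect_true(all(tr$true_area_um2 < 2.5 * 2000))
  # confluent near-convex lumina are well above the 0.3 circularity floor
  expect_true(all(tr$true_circularity >= 0.3))
})

test_that("intensity classes respect the 230/231 and whitespace boundaries", {
  s <- generate_tissue(small_slide_spec(n_cells = 30, seed = 6))
  px <- s$image$pixels
  expect_true(any(px <= 230))           # membranes present
  expect_true(any(px >= 231 & px < 245))  # lumina present
  expect_true(any(px >= 245))           # whitespace present
  # the threshold pipeline sees each truth cell as one fat object
  det <- segment_threshold(s$image, tissue = detect_tissue(s$image))
  sc <- score_detections(det, s$truth, s$image$microns_per_pixel)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$median_abs_rel_area_error, 0)
})

test_that("artefacts are generated as specified and excluded by the filters", {
  sp_art <- small_slide_spec(n_cells = 30, seed = 8,
                             n_crushed = 1, n_vessels = 1, n_specks = 1)
  s <- generate_tissue(sp_art)
  art <- s$truth[s$truth$is_artifact, ]
  expect_equal(sort(art$artifact_kind), c("crushed", "speck", "vessel"))

  crushed <- art[art$artifact_kind == "crushed", ]
  expect_lt(crushed$true_circularity, 0.3)
  expect_gte(crushed$true_area_um2, 500)
  expect_lte(crushed$true_area_um2, 20000)
  expect_lt(art$true_area_um2[art$artifact_kind == "speck"], 500)

  # the crushed region and speck never appear in edge-pipeline output:
  # count equals that of the artefact-free slide with the same seed
  s0 <- generate_tissue(small_slide_spec(n_cells = 30, seed = 8))
  d_art <- segment_edge(s$image)
  d_ref <- segment_edge(s0$image)
  expect_equal(nrow(d_art), nrow(d_ref))

  # vessels are membrane-intensity, so the threshold pipeline never reports
  # a detection at the vessel site
  d_th <- segment_threshold(s$image, tissue = detect_tissue(s$image))
  vx <- art$centroid_x_px[art$artifact_kind == "vessel"]
  vy <- art$centroid_y_px[art$artifact_kind == "vessel"]
  dist_to_vessel <- sqrt((d_th$centroid_x_px - vx)^2 + (d_th$centroid_y_px - vy)^2)
  expect_gt(min(dist_to_vessel), 15)
})

test_that("cohorts shift HFD size mass upward and write a usable manifest", {
  coh <- make_cohort(
    chow_spec = small_slide_spec(n_cells = 35),
    hfd_spec = tissue_spec(n_cells = 35, mu_log = log(3150), sigma_log = 0.45,
                           microns_per_pixel = 1, membrane_px = 3),
    n_slides_per_group = 1, base_seed = 3
  )
  expect_equal(nrow(coh$manifest), 2L)
  expect_setequal(coh$manifest$group, c("chow", "hfd"))

  chow_areas <- coh$truth$true_area_um2[coh$truth$slide_id == "chow_01"]
  hfd_areas <- coh$truth$true_area_um2[coh$truth$slide_id == "hfd_01"]
  expect_gt(mean(hfd_areas), mean(chow_areas))
  expect_gt(mean(hfd_areas > 5000), mean(chow_areas > 5000))

  out <- file.path(tempdir(), "cohort_test")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  coh2 <- make_cohort(
    chow_spec = small_slide_spec(n_cells = 10),
    hfd_spec = small_slide_spec(n_cells = 10),
    n_slides_per_group = 1, base_seed = 5, out_dir = out
  )
  expect_true(all(file.exists(coh2$manifest$image_path)))
  expect_true(file.exists(file.path(out, "truth.csv")))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  back <- read_calibrated_image(coh2$manifest$image_path[1], 1)
  expect_identical(back$pixels, coh2$slides[[1]]$image$pixels)
})

test_that("infeasible packing is rejected with a clear message", {
  sp <- tissue_spec(n_cells = 200, mu_log = log(5000), sigma_log = 0,
                    microns_per_pixel = 1, width_px = 150, height_px = 150,
                    margin_px = 20, seed = 1)
  expect_error(generate_tissue(sp), "[Ii]nfeasible packing")
})

test_that("truth matching scores degrade gracefully on corrupted detections", {
  s <- generate_tissue(small_slide_spec(n_cells = 20, seed = 12))
  det <- segment_threshold(s$image, tissue = detect_tissue(s$image))
  full <- score_detections(det, s$truth, 1)
  expect_equal(full$recall, 1)
  half <- score_detections(det[seq_len(10), ], s$truth, 1)
  expect_equal(half$recall, 0.5)
  expect_equal(half$precision, 1)
  none <- score_detections(det[0, ], s$truth, 1)
  expect_equal(none$recall, 0)
})
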