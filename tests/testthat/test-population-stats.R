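test_that("slide summaries report n, mean, SD, min, max as defined", {
  d <- tibble::tibble(area_um2 = c(1000, 2000, 3000))
  s <- summarize_slides(d)
  expect_equal(s$n_cells, 3L)
  expect_equal(s$mean_area_um2, 2000)
  expect_equal(s$sd_area_um2, 1000)
  expect_equal(s$min_area_um2, 1000)
  expect_equal(s$max_area_um2, 3000)

  one <- summarize_slides(tibble::tibble(area_um2 = 1500))
  expect_true(is.na(one$sd_area_um2))
  expect_equal(one$n_cells, 1L)

  none <- summarize_slides(tibble::tibble(area_um2 = double()))
  expect_equal(none$n_cells, 0L)
  expect_true(is.na(none$mean_area_um2))

  # invariant under permutation, grouped by slide and pipeline
  set.seed(1)
  grp <- tibble::tibble(
    slide_id = rep(c("a", "b"), each = 10),
    pipeline = "threshold",
    area_um2 = runif(20, 500, 5000)
  )
  s1 <- summarize_slides(grp)
  s2 <- summarize_slides(grp[sample(20), ])
  expect_equal(s1, s2)
  expect_equal(nrow(s1), 2L)
})

test_that("area histograms follow the floor binning rule and conserve counts", {
  h <- area_histogram(c(500, 999.9, 1000), bin_width_um2 = 500)
  expect_equal(h$count[h$bin_start == 500], 2L)
  expect_equal(h$count[h$bin_start == 1000], 1L)
  expect_equal(h$count[h$bin_start == 0], 0L)
  expect_equal(sum(h$count), 3L)
  expect_equal(sum(h$relative_frequency), 100, tolerance = 1e-9)

  single <- area_histogram(tibble::tibble(area_um2 = 1234))
  expect_equal(single$relative_frequency[single$bin_start == 1000], 100)

  set.seed(2)
  areas <- rlnorm(500, log(2000), 0.4)
  h2 <- area_histogram(areas)
  expect_equal(sum(h2$count), 500L)
  expect_equal(sum(h2$relative_frequency), 100, tolerance = 1e-9)
})

test_that("Kruskal-Wallis matches the brute-force rank statistic", {
  # independent oracle: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2,
  # valid without ties
  brute_H <- function(groups) {
    x <- unlist(groups)
    g <- rep(seq_along(groups), lengths(groups))
    r <- rank(x)
    N <- length(x)
    rb <- tapply(r, g, mean)
    ni <- lengths(groups)
    12 / (N * (N + 1)) * sum(ni * (rb - (N + 1) / 2)^2)
  }

  d <- tibble::tibble(
    area = c(1, 2, 3, 10, 11, 12),
    grp = rep(c("a", "b"), each = 3)
  )
  res <- compare_areas_kruskal(d, area, grp)
  expect_equal(res$statistic, brute_H(list(c(1, 2, 3), c(10, 11, 12))))
  expect_equal(res$statistic, 3.857142857, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:5) {
    gs <- list(runif(5), runif(7), runif(6))
    dd <- tibble::tibble(
      area = unlist(gs),
      grp = rep(letters[1:3], lengths(gs))
    )
    expect_equal(compare_areas_kruskal(dd, area, grp)$statistic, brute_H(gs),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give a null Kruskal-Wallis result and symmetric Dunn tests", {
  d <- tibble::tibble(area = rep(c(5, 6, 7, 8), 2), grp = rep(c("a", "b"), each = 4))
  res <- compare_areas_kruskal(d, area, grp)
  expect_lt(res$statistic, 1e-8)
  expect_gt(res$p_value, 0.99)
  expect_equal(tidy(res)$statistic, 0, tolerance = 1e-9)

  d3 <- tibble::tibble(area = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       grp = rep(c("a", "b", "c"), each = 3))
  res3 <- compare_areas_kruskal(d3, area, grp)
  expect_equal(nrow(tidy(res3)), 3L)
  expect_true(all(tidy(res3)$p_adjusted <= 1))
  expect_true(all(tidy(res3)$p_adjusted >= tidy(res3)$p_value - 1e-12))
  expect_equal(glance(res3)$df, 2)

  expect_error(compare_areas_kruskal(
    tibble::tibble(area = 1:3, grp = "a"), area, grp
  ), "two groups")
})

test_that("the count t-test matches its closed form", {
  # {1,2,3} vs {11,12,13}: pooled SD 1, t = -10 / sqrt(2/3)
  res <- compare_counts_ttest(c(1, 2, 3), c(11, 12, 13))
  expect_equal(res$statistic, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)

  same <- compare_counts_ttest(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_counts_ttest(1, c(1, 2)), "at least 2")

  welch <- compare_counts_ttest(c(1, 2, 3), c(11, 12, 13), var_equal = FALSE)
  expect_match(welch$method, "Welch")
})
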