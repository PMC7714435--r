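#' Per-slide detection summaries
#'
#' Summarises detections into the per-slide quantities used for group
#' statistics: the number of successfully segmented cells (the
#' adipocyte-specific sample size n) and the mean, SD (sample, n-1), minimum
#' and maximum cell area. If `slide_id` and/or `pipeline` columns are present
#' the summary is grouped by them; otherwise a single row is returned. With a
#' single detection the SD is `NA`; with no detections `n_cells` is 0 and the
#' area fields are `NA`.
#'
#' @param detections Detection tibble with an `area_um2` column, optionally
#'   `slide_id` and `pipeline`.
#'
#' @return A tibble with columns (`slide_id`, `pipeline` if present),
#'   `n_cells`, `mean_area_um2`, `sd_area_um2`, `min_area_um2`,
#'   `max_area_um2`.
#' @export
#' @examples
#' summarize_slides(tibble::tibble(area_um2 = c(1000, 2000, 3000)))
summarize_slides <- function(detections) {
  if (!"area_um2" %in% names(detections)) {
    abort("`detections` must contain an `area_um2` column.")
  }
  gv <- intersect(c("slide_id", "pipeline"), names(detections))
  if (nrow(detections) == 0 && length(gv) == 0) {
    return(tibble(
      n_cells = 0L, mean_area_um2 = NA_real_, sd_area_um2 = NA_real_,
      min_area_um2 = NA_real_, max_area_um2 = NA_real_
    ))
  }
  detections |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gv))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_area_um2 = mean(.data$area_um2),
      sd_area_um2 = if (dplyr::n() > 1) sd(.data$area_um2) else NA_real_,
      min_area_um2 = min(.data$area_um2),
      max_area_um2 = max(.data$area_um2),
      .groups = "drop"
    )
}

#' Area histogram with relative frequencies
#'
#' Bins cell areas with a fixed bin width (default 500 um^2, the population
#' binning used for adipocyte size distributions). An area `a` falls in bin
#' `floor(a / bin_width)`, i.e. bins are half-open `[k*w, (k+1)*w)`. Relative
#' frequency normalises each bin count to the total cell count of the slide,
#' as a percentage, so relative frequencies sum to 100.
#'
#' @param detections Detection tibble with an `area_um2` column, or a numeric
#'   vector of areas.
#' @param bin_width_um2 Bin width in square micrometres (default 500).
#'
#' @return A tibble of class `adipo_histogram`: `bin_start`, `bin_end`,
#'   `count`, `relative_frequency` (percent), with attributes `bin_width_um2`
#'   and `n_cells`.
#' @export
area_histogram <- function(detections, bin_width_um2 = 500) {
  if (bin_width_um2 <= 0) abort("`bin_width_um2` must be positive.")
  areas <- if (is.data.frame(detections)) detections$area_um2 else detections
  if (is.null(areas)) abort("`detections` must contain an `area_um2` column.")
  n <- length(areas)
  if (n == 0) {
    out <- tibble(
      bin_start = double(), bin_end = double(),
      count = integer(), relative_frequency = double()
    )
  } else {
    idx <- floor(areas / bin_width_um2)
    bins <- seq(0, max(idx))
    counts <- tabulate(factor(idx, levels = bins), nbins = length(bins))
    out <- tibble(
      bin_start = bins * bin_width_um2,
      bin_end = (bins + 1) * bin_width_um2,
      count = counts,
      relative_frequency = 100 * counts / n
    )
  }
  attr(out, "bin_width_um2") <- bin_width_um2
  attr(out, "n_cells") <- n
  class(out) <- c("adipo_histogram", class(out))
  out
}

#' Compare cell areas across groups (Kruskal-Wallis + Dunn)
#'
#' Nonparametric comparison of per-cell areas between methods and/or diets:
#' the tie-corrected Kruskal-Wallis rank-sum test with its asymptotic
#' chi-square p-value, followed by Dunn's pairwise z-tests on mean ranks with
#' a multiplicity adjustment across all pairs (Bonferroni by default,
#' configurable via any [stats::p.adjust()] method).
#'
#' @param data Data frame in long format.
#' @param area,group Columns holding the per-cell areas and group labels
#'   (tidy evaluation).
#' @param p_adjust Multiplicity adjustment for the Dunn tests
#'   (default `"bonferroni"`).
#'
#' @return An object of class `adipo_kruskal`. `glance()` returns the
#'   Kruskal-Wallis statistic, degrees of freedom and p-value; `tidy()`
#'   returns one row per group pair with Dunn's z and adjusted p-value.
#' @export
compare_areas_kruskal <- function(data, area, group, p_adjust = "bonferroni") {
  a <- dplyr::pull(data, {{ area }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(a) & !is.na(g)
  a <- a[keep]
  g <- as.character(g[keep])
  counts <- table(g)
  if (length(counts) < 2) abort("At least two groups are required.")
  if (any(counts < 1)) abort("Every group needs at least one observation.")

  kw <- kruskal.test(a, factor(g))

  # Dunn's pairwise comparisons on mean ranks, tie-corrected
  r <- rank(a)
  N <- length(a)
  ties <- table(a)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- names(counts)
  mean_ranks <- tapply(r, g, mean)
  pairs <- utils::combn(groups, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / counts[[p[1]]] + 1 / counts[[p[2]]]))
    (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  dunn <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    mean_rank_diff = apply(pairs, 2, function(p) mean_ranks[[p[1]]] - mean_ranks[[p[2]]]),
    statistic = z,
    p_value = p_raw,
    p_adjusted = pmin(1, p.adjust(p_raw, method = p_adjust))
  )
  structure(
    list(
      statistic = unname(kw$statistic),
      df = unname(kw$parameter),
      p_value = unname(kw$p.value),
      n = N,
      n_groups = length(groups),
      dunn = dunn,
      p_adjust = p_adjust
    ),
    class = "adipo_kruskal"
  )
}

#' @export
print.adipo_kruskal <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.4g, df = %d, p = %.3g (%d obs, %d groups)\n",
    x$statistic, x$df, x$p_value, x$n, x$n_groups
  ))
  cat(sprintf("Dunn pairwise tests (%s-adjusted):\n", x$p_adjust))
  print(x$dunn)
  invisible(x)
}

#' @rdname compare_areas_kruskal
#' @param x An `adipo_kruskal` object.
#' @param ... Unused.
#' @export
glance.adipo_kruskal <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n = x$n, n_groups = x$n_groups
  )
}

#' @rdname compare_areas_kruskal
#' @export
tidy.adipo_kruskal <- function(x, ...) x$dunn

#' Compare per-slide counts between two groups (Student's t)
#'
#' Two-sample, two-sided t-test on per-slide cell counts, equal-variance
#' (Student's) by default with Welch available.
#'
#' @param counts_a,counts_b Numeric vectors of per-slide counts, each of
#'   length at least 2.
#' @param var_equal Use the classic equal-variance Student's test
#'   (default `TRUE`); `FALSE` gives Welch's test.
#'
#' @return A one-row tibble: `estimate` (mean difference a - b), `statistic`
#'   (t), `df`, `p_value`, `mean_a`, `mean_b`, `method`.
#' @export
compare_counts_ttest <- function(counts_a, counts_b, var_equal = TRUE) {
  if (length(counts_a) < 2 || length(counts_b) < 2) {
    abort("Each group needs at least 2 observations.")
  }
  tt <- t.test(counts_a, counts_b, var.equal = var_equal)
  tibble(
    estimate = mean(counts_a) - mean(counts_b),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(counts_a),
    mean_b = mean(counts_b),
    method = tt$method
  )
}
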