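#' Pair per-slide means from two pipelines
#'
#' Aligns a slide-summary table into the paired series used by
#' [bland_altman()] and [regression_r2()]: one row per slide that was analysed
#' by both methods, with the chosen statistic from each.
#'
#' @param summaries Tibble from [summarize_slides()] with `slide_id` and
#'   `pipeline` columns.
#' @param method_x,method_y Pipeline names to pair (x and y).
#' @param value Column to compare (default `mean_area_um2`).
#'
#' @return A tibble with columns `slide_id`, `x`, `y`.
#' @export
pair_slide_means <- function(summaries, method_x, method_y, value = "mean_area_um2") {
  need <- c("slide_id", "pipeline", value)
  if (!all(need %in% names(summaries))) {
    abort(sprintf("`summaries` must contain columns: %s.", paste(need, collapse = ", ")))
  }
  wide <- summaries |>
    dplyr::filter(.data$pipeline %in% c(method_x, method_y)) |>
    dplyr::select(dplyr::all_of(c("slide_id", "pipeline", value))) |>
    tidyr::pivot_wider(names_from = "pipeline", values_from = dplyr::all_of(value))
  if (!all(c(method_x, method_y) %in% names(wide))) {
    abort("Both methods must be present in `summaries`.")
  }
  out <- tibble(
    slide_id = wide$slide_id,
    x = wide[[method_x]],
    y = wide[[method_y]]
  )
  out[stats::complete.cases(out[c("x", "y")]), , drop = FALSE]
}

#' Bland-Altman agreement between two methods
#'
#' Classic Bland-Altman analysis of paired per-slide values: differences are
#' oriented `y - x`, the bias is their mean, and the 95% limits of agreement
#' are `bias +/- 1.96 * SD` of the differences (sample SD, n-1; the
#' conventional normal-quantile multiplier with no small-sample correction).
#' On the plot the x-axis is the pairwise mean and the y-axis the difference.
#'
#' @param data Data frame holding the paired series.
#' @param x,y Columns with the two methods' values (tidy evaluation).
#' @param id Optional identifier column.
#'
#' @return An object of class `bland_altman` with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `loa_width`, `n`. `glance()` returns them as a
#'   one-row tibble; `tidy()` returns per-pair means and differences;
#'   `autoplot()` draws the agreement plot.
#' @export
#' @examples
#' d <- tibble::tibble(m1 = c(10, 20, 30), m2 = c(12, 18, 33))
#' glance(bland_altman(d, m1, m2))
bland_altman <- function(data, x, y, id = NULL) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  idv <- if (rlang::quo_is_null(enquo(id))) seq_along(xv) else dplyr::pull(data, {{ id }})
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  idv <- idv[ok]
  n <- length(xv)
  if (n < 2) abort("Bland-Altman analysis needs at least 2 complete pairs.")
  d <- yv - xv
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(
      data = tibble(id = idv, x = xv, y = yv, mean = (xv + yv) / 2, diff = d),
      bias = bias,
      sd_diff = sd_diff,
      loa_low = bias - 1.96 * sd_diff,
      loa_high = bias + 1.96 * sd_diff,
      loa_width = 2 * 1.96 * sd_diff,
      n = n,
      orientation = "y - x"
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (%s, n = %d): bias %.4g, SD %.4g, 95%% LoA [%.4g, %.4g]\n",
    x$orientation, x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    loa_width = x$loa_width, n = x$n
  )
}

#' @rdname bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' Linear regression concordance between two methods
#'
#' Ordinary least squares of method y on method x over paired per-slide
#' values, reporting slope, intercept and R^2 (the squared Pearson
#' correlation). Requires at least 3 pairs and non-constant x.
#'
#' @inheritParams bland_altman
#'
#' @return An object of class `method_regression` with fields `slope`,
#'   `intercept`, `r_squared`, `n`; `glance()`, `tidy()` and `autoplot()`
#'   methods are provided.
#' @export
regression_r2 <- function(data, x, y, id = NULL) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  idv <- if (rlang::quo_is_null(enquo(id))) seq_along(xv) else dplyr::pull(data, {{ id }})
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  idv <- idv[ok]
  if (length(xv) < 3) abort("Regression needs at least 3 complete pairs.")
  if (stats::var(xv) == 0) abort("`x` is constant; regression is undefined.")
  fit <- lm(yv ~ xv)
  r2 <- stats::cor(xv, yv)^2
  structure(
    list(
      data = tibble(id = idv, x = xv, y = yv),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      n = length(xv)
    ),
    class = "method_regression"
  )
}

#' @export
print.method_regression <- function(x, ...) {
  cat(sprintf(
    "OLS y ~ x (n = %d): slope %.4g, intercept %.4g, R^2 = %.4f\n",
    x$n, x$slope, x$intercept, x$r_squared
  ))
  invisible(x)
}

#' @rdname regression_r2
#' @export
glance.method_regression <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n = x$n
  )
}

#' @rdname regression_r2
#' @export
tidy.method_regression <- function(x, ...) x$data

#' Full pairwise agreement between two pipelines
#'
#' Convenience wrapper pairing slide summaries for two pipelines and running
#' both [bland_altman()] and [regression_r2()].
#'
#' @inheritParams pair_slide_means
#' @return A list with elements `pair` (tibble), `bland_altman`, `regression`.
#' @export
method_agreement <- function(summaries, method_x, method_y, value = "mean_area_um2") {
  pair <- pair_slide_means(summaries, method_x, method_y, value)
  list(
    pair = pair,
    bland_altman = bland_altman(pair, x, y, id = slide_id),
    regression = regression_r2(pair, x, y, id = slide_id)
  )
}
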