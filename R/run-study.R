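#' Run a full adipocyte quantification study
#'
#' End-to-end orchestration: loads (or simulates) a cohort of slides, runs the
#' requested segmentation pipelines on each, writes per-slide detection
#' tables, slide and group summaries, area histograms, and all pairwise
#' method-agreement reports, and indexes every output in a single JSON report.
#'
#' The configuration is a list (or path to a JSON file) with fields:
#' \describe{
#'   \item{out_dir}{Output directory (required).}
#'   \item{manifest}{Path to a CSV with columns `slide_id`, `image_path`,
#'     `group`, plus `microns_per_pixel` at the top level; or instead}
#'   \item{simulate}{List with `n_slides_per_group`, `base_seed`, and optional
#'     `chow` / `hfd` argument lists for [tissue_spec()]; slides are generated
#'     in memory.}
#'   \item{pipelines}{Subset of `"edge"`, `"threshold"`, `"micrograph"`
#'     (default: all three).}
#'   \item{edge, threshold, micrograph, tissue}{Optional parameter lists
#'     passed to [edge_params()], [threshold_params()], [micrograph_params()],
#'     [tissue_params()].}
#'   \item{micrograph_field_px}{Optional field size: the micrograph pipeline
#'     is run on a centred crop of this many pixels, emulating single-field
#'     acquisition; `NULL` uses the full slide.}
#' }
#'
#' Unreadable images are skipped with a warning and the run continues; a run
#' in which no slide could be processed is an error.
#'
#' @param config A list or path to a JSON configuration file.
#'
#' @return Invisibly, a list with `detections`, `summaries`, `group_summary`,
#'   `agreements`, and `report` (the report is also written to
#'   `out_dir/report.json`).
#' @export
run_study <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) abort("`config$out_dir` is required.")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "detections"), showWarnings = FALSE)

  pipelines <- config$pipelines %||% c("edge", "threshold", "micrograph")
  bad <- setdiff(pipelines, c("edge", "threshold", "micrograph"))
  if (length(bad)) abort(sprintf("Unknown pipeline(s): %s", paste(bad, collapse = ", ")))

  e_par <- do.call(edge_params, as.list(config$edge %||% list()))
  t_par <- do.call(threshold_params, as.list(config$threshold %||% list()))
  m_par <- do.call(micrograph_params, as.list(config$micrograph %||% list()))
  ts_par <- do.call(tissue_params, as.list(config$tissue %||% list()))
  field <- config$micrograph_field_px

  # --- assemble slides -------------------------------------------------------
  slides <- list()   # name -> calibrated_image
  groups <- character()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    chow <- do.call(tissue_spec, as.list(sim$chow %||% list()))
    hfd_args <- as.list(sim$hfd %||% list(mu_log = log(3150), sigma_log = 0.45))
    hfd <- do.call(tissue_spec, hfd_args)
    cohort <- make_cohort(chow, hfd,
                          n_slides_per_group = sim$n_slides_per_group %||% 3,
                          base_seed = sim$base_seed %||% 1)
    slides <- purrr::map(cohort$slides, "image")
    groups <- stats::setNames(cohort$manifest$group, cohort$manifest$slide_id)
  } else if (!is.null(config$manifest)) {
    if (is.null(config$microns_per_pixel)) {
      abort("`config$microns_per_pixel` is required with a manifest.")
    }
    man <- readr::read_csv(config$manifest, show_col_types = FALSE)
    for (i in seq_len(nrow(man))) {
      id <- man$slide_id[i]
      img <- tryCatch(
        read_calibrated_image(man$image_path[i], config$microns_per_pixel),
        error = function(e) {
          warn(sprintf("Skipping slide '%s': %s", id, conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(img)) {
        slides[[id]] <- img
        groups[id] <- if ("group" %in% names(man)) man$group[i] else NA_character_
      }
    }
  } else {
    abort("Config must provide either `manifest` or `simulate`.")
  }
  if (length(slides) == 0) abort("No slide could be processed.")

  # --- segment ---------------------------------------------------------------
  detection_files <- character()
  all_det <- purrr::imap_dfr(slides, function(img, id) {
    tissue <- if (any(c("edge", "threshold") %in% pipelines)) {
      detect_tissue(img, ts_par)
    } else NULL
    purrr::map_dfr(pipelines, function(p) {
      det <- switch(p,
        edge = segment_edge(img, e_par, tissue),
        threshold = segment_threshold(img, t_par, tissue),
        micrograph = {
          fimg <- if (!is.null(field)) crop_center(img, field, field) else img
          segment_micrograph(fimg, m_par)
        }
      )
      det <- dplyr::bind_cols(tibble(slide_id = rep(id, nrow(det))), det)
      path <- file.path(out_dir, "detections", sprintf("%s_%s.csv", id, p))
      readr::write_csv(det, path)
      detection_files <<- c(detection_files, path)
      message(sprintf("[%s] %s: %d detections", id, p, nrow(det)))
      det
    })
  })

  # --- summaries -------------------------------------------------------------
  summaries <- summarize_slides(all_det)
  readr::write_csv(summaries, file.path(out_dir, "summary.csv"))

  grp <- tibble(slide_id = names(groups), group = unname(groups))
  group_summary <- summaries |>
    dplyr::left_join(grp, by = "slide_id") |>
    dplyr::group_by(.data$group, .data$pipeline) |>
    dplyr::summarise(
      n_slides = dplyr::n(),
      mean_n_cells = mean(.data$n_cells),
      sd_n_cells = sd(.data$n_cells),
      mean_mean_area_um2 = mean(.data$mean_area_um2),
      sd_mean_area_um2 = sd(.data$mean_area_um2),
      .groups = "drop"
    )
  readr::write_csv(group_summary, file.path(out_dir, "group_summary.csv"))

  hist_df <- all_det |>
    dplyr::group_by(.data$slide_id, .data$pipeline) |>
    dplyr::group_modify(function(d, key) as_tibble(area_histogram(d))) |>
    dplyr::ungroup()
  readr::write_csv(hist_df, file.path(out_dir, "histograms.csv"))

  # --- pairwise agreement ----------------------------------------------------
  agreements <- list()
  if (length(pipelines) >= 2 && length(slides) >= 2) {
    for (pr in utils::combn(sort(pipelines), 2, simplify = FALSE)) {
      key <- paste(pr, collapse = "_vs_")
      pair <- tryCatch(pair_slide_means(summaries, pr[1], pr[2]),
                       error = function(e) NULL)
      if (is.null(pair) || nrow(pair) < 2) next
      ba <- bland_altman(pair, x, y, id = slide_id)
      reg <- tryCatch(regression_r2(pair, x, y, id = slide_id),
                      error = function(e) NULL)
      agreements[[key]] <- list(
        methods = pr,
        bland_altman = as.list(glance(ba)),
        regression = if (!is.null(reg)) as.list(glance(reg)) else NULL
      )
    }
  }
  jsonlite::write_json(agreements, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- list(
    config = config,
    n_slides = length(slides),
    pipelines = pipelines,
    files = list(
      detections = detection_files,
      summary = file.path(out_dir, "summary.csv"),
      group_summary = file.path(out_dir, "group_summary.csv"),
      histograms = file.path(out_dir, "histograms.csv"),
      agreement = file.path(out_dir, "agreement.json")
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    detections = all_det,
    summaries = summaries,
    group_summary = group_summary,
    agreements = agreements,
    report = report
  ))
}
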