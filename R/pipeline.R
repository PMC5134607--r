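# Stage orchestration and publication-style outputs. Each stage reads the
# previous stage's CSV/JSON and writes its own, so intermediate artifacts map
# onto the processing narrative: raw extraction -> filtering -> fitting with
# uncertainty -> spatial maps. A thin command-line wrapper over these
# functions ships in inst/cli/phenodesert.

#' Assemble a run configuration
#'
#' @param image_dir Directory of timestamped frames.
#' @param roi_file ROI vertex file (see [write_roi()]).
#' @param out_dir Output directory.
#' @param timestamp_pattern Filename timestamp format.
#' @param filter A [filter_config()].
#' @param n_replications Uncertainty replications (default 1000).
#' @param seed Seed recorded in every output header.
#' @param spatial Run the per-pixel analysis (default `FALSE`).
#' @param window A [histogram_window()] for the spatial stage.
#' @return A `run_config` list.
#' @export
run_config <- function(image_dir, roi_file, out_dir,
                       timestamp_pattern = "site_%Y_%m_%d_%H%M",
                       filter = filter_config(), n_replications = 1000L,
                       seed = 1L, spatial = FALSE,
                       window = histogram_window()) {
  structure(list(image_dir = image_dir, roi_file = roi_file,
                 out_dir = out_dir, timestamp_pattern = timestamp_pattern,
                 filter = filter, n_replications = as.integer(n_replications),
                 seed = as.integer(seed), spatial = isTRUE(spatial),
                 window = window),
            class = "run_config")
}

config_hash <- function(config) {
  # identifies inputs and processing settings; where outputs land is not
  # part of the identity, so reruns into different directories match
  cfg <- config[setdiff(names(config), "out_dir")]
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "")
  # small stable polynomial hash; enough to tag outputs
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 268435399
  sprintf("%07x", as.integer(h))
}

#' Write / read a pipeline stage CSV
#'
#' Stage artifacts are plain CSV prefixed with `#` header lines carrying the
#' configuration hash and seed, so reruns are traceable.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @param config The `run_config` (hash and seed go in the header).
#' @return `path` (write) or a tibble (read).
#' @export
write_stage_csv <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  writeLines(sprintf("# seed: %d", config$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_stage_csv
#' @export
read_stage_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Run the full ROI-average pipeline
#'
#' Extraction, filter chain, Gu fit with uncertainty, summary row, and
#' (optionally) the per-pixel spatial analysis; writes each stage's artifact
#' under `out_dir` and logs per-stage counts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the per-ROI summaries and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (!file.exists(config$roi_file)) {
    abort(sprintf("ROI file not found: '%s'", config$roi_file))
  }
  if (!dir.exists(config$image_dir)) {
    abort(sprintf("image directory not found: '%s'", config$image_dir))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  images <- load_image_series(config$image_dir, config$timestamp_pattern)
  inform(sprintf("stage extract: %d frame(s) indexed, %d skipped",
                 nrow(images), attr(images, "n_skipped")))
  first <- read_frame(images$path[1])
  dims <- dim(first$pixels)
  rois <- read_roi(config$roi_file)
  summaries <- list()
  paths <- character()
  for (nm in names(rois)) {
    roi <- build_roi_mask(rois[[nm]], dims[1], dims[2], name = nm)
    raw <- extract_series(images, roi)
    p_raw <- file.path(config$out_dir, sprintf("%s_raw.csv", nm))
    write_stage_csv(raw, p_raw, config)
    daily <- filter_chain(raw, config$filter)
    reports <- filter_report(daily)
    inform(sprintf(
      "stage filter [%s]: %d of %d samples retained after snow/night (threshold %.3f), %d after spline; %d days",
      nm, reports$night$n_retained, reports$night$n_input,
      reports$night$threshold, reports$spline$n_retained, nrow(daily)))
    p_daily <- file.path(config$out_dir, sprintf("%s_daily.csv", nm))
    write_stage_csv(daily, p_daily, config)
    write_filter_report(daily, file.path(config$out_dir,
                                         sprintf("%s_filters.json", nm)))
    fit <- fit_gu(daily, seed = config$seed)
    inform(sprintf("stage fit [%s]: converged = %s, rmse = %.5f",
                   nm, fit$converged, fit$rmse))
    write_fit_json(fit, file.path(config$out_dir, sprintf("%s_fit.json", nm)))
    ens <- estimate_uncertainty(fit, n = config$n_replications,
                                seed = config$seed)
    conf <- phenophase_confidence(ens)
    summaries[[nm]] <- summarize_roi(conf, fit, site = nm)
    utils::write.csv(ens$replicates,
                     file.path(config$out_dir, sprintf("%s_ensemble.csv", nm)),
                     row.names = FALSE)
    paths <- c(paths, p_raw, p_daily)
    if (config$spatial) {
      traj <- pixel_trajectories(images, roi)
      map <- fit_per_pixel(traj) |> filter_histogram(config$window)
      p_map <- file.path(config$out_dir, sprintf("%s_map.csv", nm))
      write_pheno_map(map, p_map)
      paths <- c(paths, p_map)
    }
  }
  summary_tbl <- report_summary(summaries)
  p_sum <- file.path(config$out_dir, "summary.csv")
  write_stage_csv(summary_tbl, p_sum, config)
  invisible(list(summary = summary_tbl, paths = c(paths, p_sum)))
}

#' Bind per-ROI summary records in publication column order
#'
#' @param records A list of one-row tibbles from [summarize_roi()] (or a
#'   single tibble).
#' @return A tibble with columns `site`, `ud`, `ud_lo`, `ud_hi`, `sd`, ...,
#'   `gsl`, `gsl_lo`, `gsl_hi`, `min_gcc`, `max_gcc`, `range_gcc`.
#' @export
report_summary <- function(records) {
  tbl <- if (is.data.frame(records)) records else dplyr::bind_rows(records)
  order <- c("site",
             paste0(rep(c("ud", "sd", "dd", "rd", "gsl"), each = 3),
                    c("", "_lo", "_hi")),
             "min_gcc", "max_gcc", "range_gcc")
  dplyr::select(tbl, dplyr::all_of(order))
}
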