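# End-to-end orchestration with config, logging and a reproducible
# artifact manifest. The command-line entry point at inst/cli/actirhythm
# is a thin wrapper over these functions.

#' Assemble a pipeline configuration
#'
#' @param output_dir where artifacts are written
#' @param input_dir directory of raw recording CSVs (one per participant);
#'   NULL to simulate a cohort instead
#' @param fixtures list(n_per_group, group_effects, base_config) describing
#'   the synthetic cohort used when no input directory is given
#' @param calibration list(offset, gain) applied to recordings read from
#'   disk
#' @param thresholds \code{\link{detector_thresholds}}
#' @param seed master seed
#' @param write_raw also write the simulated raw 10 Hz CSVs (large)
#' @param make_plots render the three plot types per participant
#' @param log_level "info" or "quiet"
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(output_dir, input_dir = NULL,
                            fixtures = list(n_per_group = 2),
                            calibration = list(offset = c(0, 0, 0), gain = c(1, 1, 1)),
                            thresholds = detector_thresholds(), seed = 1L,
                            write_raw = FALSE, make_plots = FALSE,
                            log_level = "info") {
  cfg <- list(output_dir = output_dir, input_dir = input_dir,
              fixtures = fixtures, calibration = calibration,
              thresholds = thresholds, seed = as.integer(seed),
              write_raw = isTRUE(write_raw), make_plots = isTRUE(make_plots),
              log_level = log_level)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file
#' @return \code{\link{pipeline_config}}
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(detector_thresholds, as.list(y$thresholds %||% list()))
  cal <- y$calibration %||% list(offset = c(0, 0, 0), gain = c(1, 1, 1))
  pipeline_config(output_dir = y$output_dir, input_dir = y$input_dir,
                  fixtures = y$fixtures %||% list(n_per_group = 2),
                  calibration = cal, thresholds = thr, seed = y$seed %||% 1L,
                  write_raw = isTRUE(y$write_raw), make_plots = isTRUE(y$make_plots),
                  log_level = y$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plog <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(format(Sys.time(), "%H:%M:%S "), ...)
}

write_csv_out <- function(df, path) {
  data.table::fwrite(data.table::as.data.table(df), path)
  path
}

#' Run the full pipeline
#'
#' Executes ingest, summarize, sleep detection, pattern extraction, group
#' statistics and (optionally) rendering for every participant, writing
#' CSV/JSON artifacts and a manifest with content hashes and a config echo.
#' Re-running with the same config and inputs reproduces the outputs
#' bit-identically.
#'
#' @param cfg \code{\link{pipeline_config}}
#' @return the manifest (list), invisibly; also written as manifest.json
#' @export
run_pipeline <- function(cfg) {
  if (is.null(cfg$output_dir)) stop("usage error: output_dir is required")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- cfg$thresholds
  plog(cfg, sprintf(
    "effective thresholds: movement<%g g, xyzvar<%g g, light<%g lux, segment>=%d min, gap<=%d min, sleep>=%d min",
    thr$movement_max, thr$xyzvar_max, thr$light_max, thr$min_segment,
    thr$max_gap, thr$min_sleep))
  files <- character()

  participants <- list()
  if (!is.null(cfg$input_dir)) {
    paths <- sort(list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE))
    if (!length(paths)) stop("usage error: no input CSV found in ", cfg$input_dir)
    for (i in seq_along(paths)) {
      plog(cfg, "ingest: ", basename(paths[i]))
      rec <- read_recording(paths[i])
      rec <- calibrate(rec, cfg$calibration)
      if (rec$fs > 10) rec <- resample_to_10hz(rec)
      participants[[i]] <- list(
        id = sub("\\.csv$", "", basename(paths[i])),
        recording = rec, truth = NULL,
        label = sub("_.*$", "", basename(paths[i])))
    }
  } else {
    fx <- cfg$fixtures
    plog(cfg, "simulate: ", fx$n_per_group %||% 2, " participants per group")
    participants <- do.call(cohort_plan, c(
      list(n_per_group = fx$n_per_group %||% 2, seed = cfg$seed),
      fx[intersect(names(fx), c("group_effects", "base_config"))]))
  }

  summaries <- list(); labels <- character()
  day_tables <- list()
  for (i in seq_along(participants)) {
    p <- participants[[i]]
    if (!is.null(p$config)) {       # simulated participant: generate on demand
      sim <- generate_recording(p$config)
      p$recording <- sim$recording
      p$truth <- sim$truth
      if (cfg$write_raw) {
        rawdir <- file.path(cfg$output_dir, "raw")
        dir.create(rawdir, showWarnings = FALSE)
        f <- file.path(rawdir, paste0(p$id, ".csv"))
        write_recording(p$recording, f)
        files <- c(files, f)
      }
    }
    plog(cfg, "process: ", p$id, " (", p$label, ")")
    bundle <- process_recording(p$recording, thr)
    f <- file.path(cfg$output_dir, paste0(p$id, "_minutes.csv"))
    md <- data.frame(timestamp = minute_times(bundle$movement),
                     movement = bundle$movement$values,
                     xyzvar = bundle$xyzvar$values,
                     light = bundle$light$values, temp = bundle$temp$values,
                     missing = bundle$movement$missing)
    files <- c(files, write_csv_out(md, f))
    sr <- bundle$sleep_records
    srd <- data.frame(night_id = sr$night_id, onset = sr$onset, offset = sr$offset,
                      n_awakenings = sr$n_awakenings, is_main = sr$is_main,
                      awakening_intervals = vapply(sr$awakenings, function(iv) {
                        jsonlite::toJSON(as.data.frame(lapply(iv, format)),
                                         auto_unbox = TRUE)
                      }, ""))
    files <- c(files, write_csv_out(srd, file.path(cfg$output_dir, paste0(p$id, "_sleep.csv"))))
    nw <- as.data.frame(bundle$nonwear)
    files <- c(files, write_csv_out(nw, file.path(cfg$output_dir, paste0(p$id, "_nonwear.csv"))))
    days <- extract_all(bundle)
    day_tables[[p$id]] <- days
    files <- c(files, write_csv_out(days, file.path(cfg$output_dir, paste0(p$id, "_patterns.csv"))))
    if (any(days$valid)) {
      summaries[[length(summaries) + 1L]] <- summarize_participant(days)
      labels <- c(labels, p$label)
    }
    if (!is.null(p$truth)) {
      diary <- write_diary(p$truth, report_noise_sd = 0, seed = cfg$seed)
      ev <- evaluate_against_diary(bundle$sleep_records, diary)
      files <- c(files, write_csv_out(ev$per_night,
                                      file.path(cfg$output_dir, paste0(p$id, "_diary_eval.csv"))))
    }
    if (cfg$make_plots) {
      files <- c(files,
        file.path(cfg$output_dir, paste0(p$id, "_summary.png")),
        file.path(cfg$output_dir, paste0(p$id, "_actogram.png")),
        file.path(cfg$output_dir, paste0(p$id, "_colored.png")))
      data_summary_plot(bundle, rec = p$recording,
                        path = file.path(cfg$output_dir, paste0(p$id, "_summary.png")))
      actogram(bundle, path = file.path(cfg$output_dir, paste0(p$id, "_actogram.png")))
      colored_actogram(bundle, path = file.path(cfg$output_dir, paste0(p$id, "_colored.png")))
    }
    rm(bundle); gc(verbose = FALSE)
  }

  f <- file.path(cfg$output_dir, "pattern_definitions.json")
  jsonlite::write_json(pattern_definitions(), f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  if (length(unique(labels)) >= 2L && all(table(labels) >= 3L)) {
    plog(cfg, "compare: ", length(summaries), " participants")
    report <- pairwise_group_report(summaries, labels)
    files <- c(files, write_csv_out(report, file.path(cfg$output_dir, "group_report.csv")))
  } else {
    plog(cfg, "compare: skipped (need >= 2 groups with >= 3 participants each)")
  }

  manifest <- list(
    config = list(seed = cfg$seed, thresholds = unclass(thr),
                  fixtures = cfg$fixtures, input_dir = cfg$input_dir),
    files = lapply(sort(unique(files)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  plog(cfg, "done: ", length(manifest$files), " artifacts in ", cfg$output_dir)
  invisible(manifest)
}
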