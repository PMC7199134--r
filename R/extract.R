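# Participant-level orchestration: preprocessed bundle -> day-pattern table.

#' Preprocess a recording into a participant bundle
#'
#' Runs non-wear detection (unless supplied), per-minute summaries and the
#' sleep detector, returning everything the pattern extractor needs.
#'
#' @param rec calibrated triaxial_recording at 10 Hz
#' @param thr \code{\link{detector_thresholds}}
#' @param nonwear optional precomputed \code{\link{interval_set}}
#' @param align detector window alignment (see
#'   \code{\link{sleep_candidates}})
#' @return list of class \code{participant_bundle}: minute series
#'   (\code{movement}, \code{xyzvar}, \code{light}, \code{temp}),
#'   \code{sleep_records}, \code{nonwear}, \code{thr}, \code{align}
#' @export
process_recording <- function(rec, thr = detector_thresholds(), nonwear = NULL,
                              align = "center") {
  if (!isTRUE(rec$calibrated)) stop("recording must be calibrated first")
  if (rec$fs != 10) stop("recording must be resampled to 10 Hz first")
  if (is.null(nonwear)) nonwear <- detect_nonwear(rec)
  movement <- movement_series(rec, nonwear)
  xyzvar <- xyz_variation_series(rec, nonwear)
  mods <- minute_modalities(rec, nonwear)
  records <- detect_sleep(movement, xyzvar, mods$light, thr, align)
  structure(list(movement = movement, xyzvar = xyzvar, light = mods$light,
                 temp = mods$temp, sleep_records = records, nonwear = nonwear,
                 thr = thr, align = align),
            class = "participant_bundle")
}

day_indices <- function(series, date) {
  # minute indices of civil day `date` (midnight-midnight) within the series
  t0 <- as.numeric(acti_time(paste(date, "00:00:00")))
  i0 <- as.integer(round((t0 - as.numeric(series$start)) / 60)) + 1L
  i0:(i0 + 1439L)
}

interval_day_idx <- function(start, end, date, series) {
  # indices within civil day `date` covered by [start, end)
  idx <- day_indices(series, date)
  tt <- as.numeric(series$start) + (idx - 1) * 60
  which(tt >= as.numeric(start) & tt < as.numeric(end))
}

#' Extract the full day-pattern table for one participant
#'
#' One row per complete midnight-to-midnight day in the recording. A day is
#' invalid (all patterns missing) when more than \code{max_nonwear_frac} of
#' it is non-wear or when the night starting that evening has no detected
#' main sleep. The diurnal window runs from the previous night's main-sleep
#' offset (rise time) to the current night's main-sleep onset (bed time);
#' diurnal features are missing when either boundary is unavailable.
#' Sleep onset/offset are reported on a continuous clock in hours where
#' times after midnight exceed 24 (so 00:30 is 24.5), which keeps
#' cross-night averages meaningful.
#'
#' @param bundle \code{\link{process_recording}} output
#' @param max_nonwear_frac maximum tolerated non-wear fraction per day
#' @return data.frame: \code{date}, \code{valid}, then the 50
#'   \code{\link{pattern_registry}} columns in fixed order
#' @export
extract_all <- function(bundle, max_nonwear_frac = 0.2) {
  mv <- bundle$movement
  n_min <- length(mv)
  t0 <- as.numeric(mv$start)
  first_day <- as.Date(ceiling(t0 / 86400), origin = "1970-01-01")
  last_end <- t0 + n_min * 60
  n_days <- floor((last_end - as.numeric(acti_time(paste(first_day, "00:00:00")))) / 86400)
  reg <- pattern_registry()
  if (n_days < 1L) {
    warning("no complete midnight-to-midnight day in the recording")
    out <- data.frame(date = as.Date(character()), valid = logical())
    out[reg] <- lapply(reg, function(.) numeric(0))
    return(out)
  }
  dates <- first_day + seq_len(n_days) - 1L
  main <- bundle$sleep_records[bundle$sleep_records$is_main, , drop = FALSE]
  phases <- if (nrow(main)) phase_differences(bundle$sleep_records) else NULL
  is1 <- interday_stability(mv$values, mv$start, "IS1")
  is2 <- interday_stability(mv$values, mv$start, "IS2")

  rows <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    date <- dates[d]
    vals <- setNames(rep(NA_real_, length(reg)), reg)
    idx <- day_indices(mv, date)
    day_mv <- mv$values[idx]
    nw_frac <- overlap_minutes(acti_time(paste(date, "00:00:00")),
                               acti_time(paste(date, "00:00:00")) + 86400,
                               bundle$nonwear) / 1440
    night_cur <- main[main$night_id == date, , drop = FALSE]
    night_prev <- main[main$night_id == (date - 1L), , drop = FALSE]
    valid <- nw_frac <= max_nonwear_frac && nrow(night_cur) == 1L
    if (valid) {
      npr <- nonparametric_rhythm(day_mv)
      vals[c("M10", "M10_time", "L5", "L5_time", "RA")] <-
        unlist(npr[c("M10", "M10_time", "L5", "L5_time", "RA")])
      vals["IS1"] <- is1; vals["IS2"] <- is2
      vals["IV1"] <- intraday_variability(day_mv, "IV1")
      vals["IV2"] <- intraday_variability(day_mv, "IV2")
      vals["IV3"] <- intraday_variability(day_mv, "IV3")
      cm <- cmse(day_mv)
      vals[names(cm)] <- cm

      sleep_idx <- integer(0)
      for (r in seq_len(nrow(night_prev))) {
        sleep_idx <- c(sleep_idx, interval_day_idx(night_prev$onset[r], night_prev$offset[r], date, mv))
      }
      sleep_idx <- c(sleep_idx, interval_day_idx(night_cur$onset[1], night_cur$offset[1], date, mv))
      sleep_idx <- sort(unique(sleep_idx))
      diurnal_idx <- if (nrow(night_prev) == 1L) {
        interval_day_idx(night_prev$offset[1], night_cur$onset[1], date, mv)
      } else integer(0)
      if (length(diurnal_idx) >= 3L) {
        vals[c("tkeo_diurnal", "tkeo_ratio")] <- unlist(tkeo_features(day_mv, diurnal_idx))
        vals[c("rmssd_diurnal", "rmssd_ratio")] <- unlist(rmssd_features(day_mv, diurnal_idx))
        df <- distribution_features(day_mv, diurnal_idx, sleep_idx)
        vals[names(df)] <- unlist(df)
      }

      met <- sleep_metrics(night_cur[1, ], mv, bundle$thr, bundle$align)
      noon <- acti_time(paste(date, "12:00:00"))
      vals["sleep_onset"] <- 12 + as.numeric(met$onset - noon, units = "hours")
      vals["sleep_offset"] <- 12 + as.numeric(met$offset - noon, units = "hours")
      vals["sleep_duration"] <- met$duration_min
      vals["n_wake_ups"] <- met$number_wake_ups
      vals["waso_minutes"] <- met$waso_minutes
      vals["sleep_entropy"] <- met$sleep_entropy
      vals[c("sleep_p5", "sleep_p25", "sleep_p50", "sleep_p75", "sleep_p95")] <-
        unlist(met[c("sleep_p5", "sleep_p25", "sleep_p50", "sleep_p75", "sleep_p95")])
      vals["awakenings_total_minutes"] <- met$awakenings_total_minutes

      tf <- temperature_sleep_features(bundle$temp, night_cur[1, ])
      vals[names(tf)] <- unlist(tf)
      if (!is.null(phases)) {
        ph <- phases[phases$night_id == date, , drop = FALSE]
        if (nrow(ph) == 1L) {
          vals["onset_phase"] <- ph$onset_phase
          vals["offset_phase"] <- ph$offset_phase
        }
      }
      cf <- cosinor_fit(day_mv)
      vals["cosinor_mesor"] <- cf$mesor
      vals["cosinor_amplitude"] <- cf$amplitude
      vals["cosinor_phase"] <- cf$acrophase
    }
    rows[[d]] <- c(list(date = date, valid = valid), as.list(vals))
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (!any(out$valid)) warning("no valid day for this participant")
  rownames(out) <- NULL
  out
}

#' Units and definitions of the pattern registry
#'
#' @return data.frame(name, unit, description) suitable as a JSON sidecar
#' @export
pattern_definitions <- function() {
  reg <- pattern_registry()
  unit <- setNames(rep("g", length(reg)), reg)
  unit[c("M10_time", "L5_time", "sleep_onset", "sleep_offset",
         "temp_zenith_time", "temp_nadir_time", "cosinor_phase")] <- "clock hours"
  unit[c("RA", "pct_nocturnal_activity", "IS1", "IS2", "IV1", "IV2", "IV3",
         "diurnal_skewness", "tkeo_ratio", "rmssd_ratio",
         "cmse_5", "cmse_30", "cmse_60", "cmse_120", "sleep_entropy")] <- "dimensionless"
  unit[c("sleep_duration", "waso_minutes", "awakenings_total_minutes",
         "onset_phase", "offset_phase")] <- "minutes"
  unit["n_wake_ups"] <- "count"
  unit[c("temp_zenith", "temp_nadir", "temp_range")] <- "degC"
  unit[c("tkeo_diurnal")] <- "g^2"
  desc <- c(
    M10 = "mean activity of the 10 most active hours",
    M10_time = "start time of the 10 most active hours",
    L5 = "mean activity of the 5 least active hours",
    L5_time = "start time of the 5 least active hours",
    RA = "relative amplitude (M10-L5)/(M10+L5)",
    MDA = "mean diurnal activity (rise time to bed time)",
    MNA = "mean nocturnal activity (within main sleep)",
    MA = "mean 24-h activity",
    diurnal_skewness = "sample skewness of diurnal activity",
    pct_nocturnal_activity = "nocturnal / total 24-h activity",
    IS1 = "interday stability, hourly bins",
    IS2 = "interday stability, hourly bins stepped by 30 min",
    IV1 = "intraday variability, hourly",
    IV2 = "intraday variability, minute level",
    IV3 = "intraday variability, hourly stepped by 30 min",
    tkeo_diurnal = "mean Teager-Kaiser energy, diurnal window",
    tkeo_ratio = "diurnal / 24-h mean Teager-Kaiser energy",
    rmssd_diurnal = "RMS of successive differences, diurnal window",
    rmssd_ratio = "diurnal / 24-h RMSSD",
    sleep_onset = "clock time of falling asleep (continuous hours)",
    sleep_offset = "clock time of final waking (continuous hours)",
    sleep_duration = "main sleep duration",
    n_wake_ups = "number of awakenings during main sleep",
    waso_minutes = "minutes awake (movement rule) inside sleep",
    sleep_entropy = "entropy of sleep activity histogram",
    awakenings_total_minutes = "summed awakening durations",
    temp_zenith = "max wrist temperature during sleep",
    temp_zenith_time = "time of max sleep temperature",
    temp_nadir = "min wrist temperature during sleep",
    temp_nadir_time = "time of min sleep temperature",
    temp_range = "zenith minus nadir",
    onset_phase = "night-to-night change in sleep onset time",
    offset_phase = "night-to-night change in sleep offset time",
    cosinor_mesor = "rhythm-adjusted mean of the fitted 24-h sinusoid",
    cosinor_amplitude = "amplitude of the fitted 24-h sinusoid",
    cosinor_phase = "acrophase (time of fitted peak)")
  per <- function(p, what) sprintf("%s percentile of %s activity", p, what)
  for (p in c(5, 25, 50, 75, 95)) {
    desc[sprintf("diurnal_p%d", p)] <- per(p, "diurnal")
    desc[sprintf("sleep_p%d", p)] <- per(p, "sleep")
  }
  for (s in c(5, 30, 60, 120)) {
    desc[sprintf("cmse_%d", s)] <- sprintf("composite multiscale sample entropy, %d-min scale", s)
  }
  data.frame(name = reg, unit = unname(unit[reg]), description = unname(desc[reg]))
}

#' Summarize a participant's day-pattern table
#'
#' Per-pattern mean and sample SD across valid days, missing values skipped
#' per pattern.
#'
#' @param day_table output of \code{\link{extract_all}}
#' @return list(mean, sd, n_valid_days) with named numeric vectors over the
#'   registry
#' @export
summarize_participant <- function(day_table) {
  valid <- day_table[day_table$valid, , drop = FALSE]
  if (!nrow(valid)) stop("no valid day to summarize")
  reg <- pattern_registry()
  m <- vapply(reg, function(p) {
    v <- valid[[p]]; v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, 1)
  s <- vapply(reg, function(p) {
    v <- valid[[p]]; v <- v[!is.na(v)]
    if (length(v) >= 2L) sd(v) else NA_real_
  }, 1)
  list(mean = m, sd = s, n_valid_days = nrow(valid))
}
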