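# Three-rule light-assisted sleep detection with awakening recovery,
# night assignment, per-sleep metrics and sleep-diary evaluation.

#' Detector thresholds
#'
#' Defaults follow the empirical rules the framework was built around:
#' rolling 10-min median movement below 0.07, rolling 5-min mean xyz
#' variation below 0.1, rolling 5-min mean light below 30 lux; candidate
#' segments of at least 30 min joined across gaps of up to 30 min (the gap
#' recorded as an awakening); merged blocks spanning less than 2 h removed.
#'
#' @param movement_max movement rule threshold (g)
#' @param xyzvar_max xyz-variation rule threshold (g)
#' @param light_max light rule threshold (lux)
#' @param min_segment minimum candidate-run length to keep (min)
#' @param max_gap maximum joinable gap between runs (min)
#' @param min_sleep minimum span of a retained sleep block (min)
#' @return list of class \code{detector_thresholds}
#' @export
detector_thresholds <- function(movement_max = 0.07, xyzvar_max = 0.1,
                                light_max = 30, min_segment = 30,
                                max_gap = 30, min_sleep = 120) {
  thr <- list(movement_max = movement_max, xyzvar_max = xyzvar_max,
              light_max = light_max, min_segment = as.integer(min_segment),
              max_gap = as.integer(max_gap), min_sleep = as.integer(min_sleep))
  if (any(unlist(thr) <= 0)) stop("all detector thresholds must be positive")
  if (thr$min_sleep < thr$min_segment) stop("min_sleep must be >= min_segment")
  class(thr) <- "detector_thresholds"
  thr
}

#' Per-minute sleep-candidate mask
#'
#' A minute is a sleep candidate iff all three rules hold strictly:
#' rolling 10-min median movement < \code{movement_max}, rolling 5-min mean
#' xyz variation < \code{xyzvar_max}, and rolling 5-min mean light <
#' \code{light_max}. Minutes whose smoothed inputs are missing are never
#' candidates. With \code{use_light = FALSE} the light rule is skipped (for
#' devices without an ambient light channel) with a loud warning, since
#' sedentary wake is then easily mislabelled as sleep.
#'
#' @param movement,xyzvar,light \code{\link{minute_series}} on a shared
#'   time base
#' @param thr \code{\link{detector_thresholds}}
#' @param align alignment of the smoothing windows: \code{"center"}
#'   (default; detection is offline, and centred windows keep rule
#'   transitions unbiased in time) or \code{"right"}
#' @param use_light logical; set FALSE only when no light channel exists
#' @return logical \code{\link{minute_series}}
#' @export
sleep_candidates <- function(movement, xyzvar, light,
                             thr = detector_thresholds(),
                             align = c("center", "right"), use_light = TRUE) {
  align <- match.arg(align)
  if (use_light) stopifnot_same_base(movement, xyzvar, light) else stopifnot_same_base(movement, xyzvar)
  mv <- rolling_stat(movement, 10, "median", align)$values
  xv <- rolling_stat(xyzvar, 5, "mean", align)$values
  cand <- (mv < thr$movement_max) & (xv < thr$xyzvar_max)
  if (use_light) {
    lv <- rolling_stat(light, 5, "mean", align)$values
    cand <- cand & (lv < thr$light_max)
  } else {
    warning("no ambient light channel: running in two-rule mode; sedentary ",
            "wake may be mislabelled as sleep")
  }
  cand[is.na(cand)] <- FALSE
  minute_series(movement$start, cand, missing = rep(FALSE, length(cand)))
}

#' Merge candidate runs into sleep blocks and record awakenings
#'
#' Maximal candidate runs shorter than \code{min_segment} minutes are
#' discarded outright (they neither extend sleep nor shorten awakenings).
#' The remaining runs are joined left to right whenever the gap between
#' consecutive runs is at most \code{max_gap} minutes; each joined gap is
#' recorded as an awakening. Merged blocks whose total span (onset to
#' offset, awakenings included) is below \code{min_sleep} minutes are
#' removed.
#'
#' @param mask logical \code{\link{minute_series}} from
#'   \code{\link{sleep_candidates}}
#' @param thr \code{\link{detector_thresholds}}
#' @return data.frame with columns \code{onset}, \code{offset} (POSIXct),
#'   \code{n_awakenings} and list-column \code{awakenings}
#'   (\code{\link{interval_set}} per block)
#' @export
merge_candidates <- function(mask, thr = detector_thresholds()) {
  v <- as.logical(mask$values); v[is.na(v)] <- FALSE
  r <- rle(v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= thr$min_segment
  rs <- starts[keep]; re <- ends[keep]            # runs in minutes (inclusive)
  empty <- data.frame(onset = acti_time(character()), offset = acti_time(character()),
                      n_awakenings = integer())
  empty$awakenings <- list()
  if (!length(rs)) return(empty)
  blocks <- list(); cur_s <- rs[1]; cur_e <- re[1]; cur_aw <- list()
  flush <- function() {
    span <- cur_e - cur_s + 1L
    if (span >= thr$min_sleep) {
      aw <- if (length(cur_aw)) {
        m <- do.call(rbind, cur_aw)
        interval_set(mask$start + (m[, 1] - 1L) * 60, mask$start + (m[, 2] - 1L) * 60)
      } else interval_set()
      blocks[[length(blocks) + 1L]] <<- list(s = cur_s, e = cur_e, aw = aw)
    }
  }
  for (i in seq_along(rs)[-1]) {
    gap <- rs[i] - cur_e - 1L
    if (gap <= thr$max_gap) {
      cur_aw[[length(cur_aw) + 1L]] <- c(cur_e + 1L, rs[i])  # [end+1, next start)
      cur_e <- re[i]
    } else {
      flush()
      cur_s <- rs[i]; cur_e <- re[i]; cur_aw <- list()
    }
  }
  flush()
  if (!length(blocks)) return(empty)
  out <- data.frame(
    onset = mask$start + (vapply(blocks, `[[`, 1L, "s") - 1L) * 60,
    offset = mask$start + vapply(blocks, `[[`, 1L, "e") * 60,
    n_awakenings = vapply(blocks, function(b) nrow(b$aw), 1L))
  out$awakenings <- lapply(blocks, `[[`, "aw")
  out
}

noon_window_id <- function(times, origin_date = NULL) {
  # date of the noon that starts the noon-to-noon window containing `times`
  as.Date(floor(as.numeric(times) / 86400 - 0.5), origin = "1970-01-01")
}

#' Assign sleep blocks to nights (noon-to-noon windows)
#'
#' Within each noon-to-noon local window, the block with the longest span
#' whose onset falls in the window is the main (nocturnal) sleep; ties go
#' to the earlier onset. Other blocks are naps/secondary sleep.
#'
#' @param blocks data.frame from \code{\link{merge_candidates}}
#' @param span_start,span_end POSIXct recording span (used to enumerate
#'   windows so nights without any block are reported)
#' @return data.frame of sleep records: \code{night_id} (Date of the noon
#'   starting the window), \code{onset}, \code{offset},
#'   \code{n_awakenings}, \code{is_main}, list-column \code{awakenings}.
#'   Attribute \code{missing_nights}: Dates of windows with no block.
#' @export
assign_nights <- function(blocks, span_start, span_end) {
  all_nights <- unique(noon_window_id(seq(as.numeric(acti_time(span_start)),
                                          as.numeric(acti_time(span_end)) - 1,
                                          by = 43200)))
  if (!nrow(blocks)) {
    out <- blocks
    out$night_id <- as.Date(character()); out$is_main <- logical()
    attr(out, "missing_nights") <- all_nights
    return(out)
  }
  nid <- noon_window_id(blocks$onset)
  span <- as.numeric(blocks$offset - blocks$onset, units = "mins")
  is_main <- logical(nrow(blocks))
  for (d in unique(nid)) {
    i <- which(nid == d)
    best <- i[order(-span[i], as.numeric(blocks$onset[i]))][1]
    is_main[best] <- TRUE
  }
  out <- blocks
  out$night_id <- nid
  out$is_main <- is_main
  out <- out[order(out$onset), c("night_id", "onset", "offset",
                                 "n_awakenings", "is_main", "awakenings")]
  rownames(out) <- NULL
  attr(out, "missing_nights") <- as.Date(setdiff(all_nights, nid), origin = "1970-01-01")
  out
}

#' Run the full sleep detector on minute series
#'
#' Convenience wrapper: candidates, merging, night assignment.
#'
#' @inheritParams sleep_candidates
#' @return sleep records as from \code{\link{assign_nights}}
#' @export
detect_sleep <- function(movement, xyzvar, light, thr = detector_thresholds(),
                         align = c("center", "right"), use_light = TRUE) {
  align <- match.arg(align)
  mask <- sleep_candidates(movement, xyzvar, light, thr, align, use_light)
  blocks <- merge_candidates(mask, thr)
  assign_nights(blocks, movement$start, movement$start + length(movement) * 60)
}

#' Per-sleep metrics for one main sleep record
#'
#' Two distinct fragmentation totals are reported: the joined-gap total
#' (\code{awakenings_total_minutes}, summed durations of recorded
#' awakenings) and WASO minutes (minutes inside the sleep window whose
#' rolling 10-min median movement breaks the candidate movement rule; a
#' movement-based superset that can also catch restlessness that never
#' split the candidate mask). Sleep entropy is the natural-log Shannon
#' entropy of the movement histogram over fixed absolute bins (60 bins on
#' [0, 3] g plus overflow), so values are comparable across participants.
#'
#' @param record one row of the sleep-record data.frame (with is_main TRUE)
#' @param movement movement \code{\link{minute_series}}
#' @param thr \code{\link{detector_thresholds}}
#' @param align alignment used for the movement rule (match the detector)
#' @return named list of metrics
#' @export
sleep_metrics <- function(record, movement, thr = detector_thresholds(),
                          align = c("center", "right")) {
  align <- match.arg(align)
  onset <- record$onset; offset <- record$offset
  dur <- as.numeric(offset - onset, units = "mins")
  if (dur < thr$min_sleep) stop("sleep record shorter than ", thr$min_sleep, " min")
  aw <- record$awakenings[[1]]
  i0 <- as.numeric(onset - movement$start, units = "mins") + 1L
  i1 <- as.numeric(offset - movement$start, units = "mins")
  i0 <- max(1L, as.integer(round(i0))); i1 <- min(length(movement), as.integer(round(i1)))
  mv <- movement$values[i0:i1]
  med <- rolling_stat(movement, 10, "median", align)$values[i0:i1]
  waso <- sum(med >= thr$movement_max, na.rm = TRUE)
  x <- mv[!is.na(mv)]
  edges <- c(seq(0, 3, by = 0.05), Inf)
  p <- tabulate(findInterval(x, edges, rightmost.closed = FALSE), length(edges) - 1L)
  p <- p[p > 0] / length(x)
  entropy <- if (length(x)) -sum(p * log(p)) else NA_real_
  qs <- if (length(x)) quantile(x, c(.05, .25, .5, .75, .95), names = FALSE, type = 7)
        else rep(NA_real_, 5)
  list(onset = onset, offset = offset, duration_min = dur,
       number_wake_ups = nrow(aw),
       awakenings_total_minutes = interval_minutes(aw),
       waso_minutes = waso, sleep_entropy = entropy,
       sleep_p5 = qs[1], sleep_p25 = qs[2], sleep_p50 = qs[3],
       sleep_p75 = qs[4], sleep_p95 = qs[5])
}

#' Evaluate detected sleep against a sleep diary
#'
#' Errors are detected minus reported, in minutes, so negative onset errors
#' mean the algorithm placed sleep onset earlier than the diary. The
#' summary reports median and IQR per cohort. When a second method's
#' records are supplied, Bland-Altman pairs (mean of the two estimates vs
#' their difference, minutes) are emitted for onset and offset.
#'
#' @param records sleep records (from \code{\link{assign_nights}}); only
#'   main records are matched
#' @param diary data.frame(night_id, onset, offset, ...) as from
#'   \code{\link{write_diary}}
#' @param other optional second method's records (night_id, onset, offset)
#' @return list(per_night, summary, bland_altman)
#' @export
evaluate_against_diary <- function(records, diary, other = NULL) {
  main <- records[records$is_main, , drop = FALSE]
  m <- match(diary$night_id, main$night_id)
  per_night <- data.frame(
    night_id = diary$night_id,
    matched = !is.na(m),
    onset_error = as.numeric(main$onset[m] - diary$onset, units = "mins"),
    offset_error = as.numeric(main$offset[m] - diary$offset, units = "mins"))
  unmatched_detected <- setdiff(main$night_id, diary$night_id)
  ok <- per_night$matched
  summary <- data.frame(
    measure = c("onset_error", "offset_error"),
    median = c(median(per_night$onset_error[ok]), median(per_night$offset_error[ok])),
    iqr = c(IQR(per_night$onset_error[ok]), IQR(per_night$offset_error[ok])),
    n = sum(ok))
  ba <- NULL
  if (!is.null(other)) {
    om <- match(main$night_id, other$night_id)
    keep <- !is.na(om)
    a_on <- as.numeric(main$onset[keep]); b_on <- as.numeric(other$onset[om[keep]])
    a_of <- as.numeric(main$offset[keep]); b_of <- as.numeric(other$offset[om[keep]])
    ba <- data.frame(
      night_id = main$night_id[keep],
      measure = rep(c("onset", "offset"), each = sum(keep)),
      mean = c((a_on + b_on) / 2, (a_of + b_of) / 2) / 60,
      difference = c(a_on - b_on, a_of - b_of) / 60)
  }
  list(per_night = per_night, summary = summary, bland_altman = ba,
       unmatched_detected = unmatched_detected)
}
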