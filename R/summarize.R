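# Collapse 10 Hz triaxial data into the per-minute summary variables the
# detector and the pattern registry work on.

minute_count <- function(rec) floor(n_samples(rec) / (rec$fs * 60))

nonwear_mask <- function(rec, nonwear, n_min) {
  if (is.null(nonwear)) rep(FALSE, n_min) else minutes_overlapping(nonwear, rec$start, n_min)
}

#' Per-minute movement summary of a triaxial recording
#'
#' For each non-overlapping minute, movement is the square root of the sum
#' of squared successive differences of the three acceleration axes taken
#' within the minute (599 differences per axis at 10 Hz). Differencing
#' before the Euclidean norm emphasises changes of wrist position and
#' suppresses the static gravity component and slow drift. Minutes
#' overlapping non-wear are missing.
#'
#' @param rec calibrated triaxial_recording
#' @param nonwear optional \code{\link{interval_set}} of non-wear episodes
#' @return \code{\link{minute_series}} of movement values (g)
#' @export
movement_series <- function(rec, nonwear = NULL) {
  spm <- as.integer(rec$fs * 60)
  n_min <- minute_count(rec)
  if (n_min < 1L) {
    warning("recording shorter than one minute; empty movement series")
    return(minute_series(rec$start, numeric(0)))
  }
  vals <- .block_movement_c(rec$x, rec$y, rec$z, spm, n_min)
  vals[nonwear_mask(rec, nonwear, n_min)] <- NA
  minute_series(rec$start, vals)
}

# Per-minute mean of each acceleration axis (n_min x 3 matrix, NA on nonwear).
minute_axis_means <- function(rec, nonwear = NULL) {
  spm <- as.integer(rec$fs * 60)
  n_min <- minute_count(rec)
  n <- n_min * spm
  m <- cbind(colMeans(matrix(rec$x[1:n], nrow = spm)),
             colMeans(matrix(rec$y[1:n], nrow = spm)),
             colMeans(matrix(rec$z[1:n], nrow = spm)))
  m[nonwear_mask(rec, nonwear, n_min), ] <- NA
  m
}

#' Per-minute xyz variation (slow postural variation summary)
#'
#' Three stages: (1) mean acceleration per axis per minute; (2) Euclidean
#' norm of the differences between successive minute means; (3) rolling
#' 10-min median of those norms advanced by one minute (90% window
#' overlap), right-aligned. The result tracks slow changes of arm posture
#' rather than fast within-minute jitter.
#'
#' @inheritParams movement_series
#' @return \code{\link{minute_series}}; the first 10 minutes are missing by
#'   construction
#' @export
xyz_variation_series <- function(rec, nonwear = NULL) {
  n_min <- minute_count(rec)
  if (n_min < 11L) {
    warning("fewer than 11 minutes of data; empty xyz variation series")
    return(minute_series(rec$start, rep(NA_real_, max(n_min, 0L))))
  }
  m <- minute_axis_means(rec, nonwear)
  d <- sqrt(rowSums(apply(m, 2, diff)^2))
  v <- c(NA_real_, d)                  # aligned to the later minute
  rolling_stat(minute_series(rec$start, v), 10, "median", "right")
}

#' Per-minute light and temperature summaries
#'
#' Per-minute means of the light and temperature channels. Non-wear minutes
#' are missing for temperature (the sensor is off-body) but retained for
#' light (ambient light remains meaningful).
#'
#' @inheritParams movement_series
#' @return list with elements \code{light} and \code{temp}
#'   (\code{\link{minute_series}})
#' @export
minute_modalities <- function(rec, nonwear = NULL) {
  spm <- as.integer(rec$fs * 60)
  n_min <- minute_count(rec)
  n <- n_min * spm
  lt <- colMeans(matrix(rec$light[1:n], nrow = spm))
  tp <- colMeans(matrix(rec$temp[1:n], nrow = spm))
  tp[nonwear_mask(rec, nonwear, n_min)] <- NA
  list(light = minute_series(rec$start, lt),
       temp = minute_series(rec$start, tp))
}
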