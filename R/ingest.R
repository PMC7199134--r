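# Reading, calibrating, resampling and non-wear masking of raw recordings.

new_triaxial_recording <- function(start, fs, x, y, z, light, temp,
                                   calibrated = FALSE) {
  n <- length(x)
  if (!all(c(length(y), length(z), length(light), length(temp)) == n)) {
    stop("all channels must have the same length")
  }
  if (!(fs > 0)) stop("fs must be > 0")
  structure(list(start = acti_time(start), fs = fs, x = x, y = y, z = z,
                 light = light, temp = temp, calibrated = isTRUE(calibrated)),
            class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording: %d samples @ %g Hz from %s (%.2f days), %scalibrated>\n",
              length(x$x), x$fs, format(x$start),
              length(x$x) / x$fs / 86400, if (x$calibrated) "" else "un"))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec triaxial_recording
#' @export
n_samples <- function(rec) length(rec$x)

#' Write a recording to timestamped CSV
#'
#' Columns: \code{timestamp} (ISO 8601 with fractional seconds), \code{x},
#' \code{y}, \code{z} (g), \code{light} (lux), \code{temp} (degC).
#'
#' @param rec triaxial_recording
#' @param path output file path
#' @return the path, invisibly
#' @export
write_recording <- function(rec, path) {
  n <- n_samples(rec)
  step <- 1 / rec$fs
  secs <- as.numeric(rec$start) + (seq_len(n) - 1) * step
  # fast ISO timestamps: per-second prefix + fixed fractional suffix
  whole <- floor(secs + 1e-9)
  frac <- round((secs - whole) * rec$fs) / rec$fs
  uw <- unique(whole)
  pref <- format(as.POSIXct(uw, origin = "1970-01-01", tz = .acti_tz),
                 "%Y-%m-%dT%H:%M:%S")
  ts <- paste0(pref[match(whole, uw)], substring(sprintf("%.3f", frac), 2))
  dt <- data.table::data.table(timestamp = ts, x = rec$x, y = rec$y, z = rec$z,
                               light = rec$light, temp = rec$temp)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a raw recording from timestamped CSV
#'
#' Expects columns \code{timestamp,x,y,z,light,temp} with strictly monotone
#' timestamps; the sampling rate is inferred from the median timestamp step.
#' The result is marked uncalibrated.
#'
#' @param path CSV file path
#' @param format input format; only \code{"raw-csv"} is supported
#' @return triaxial_recording
#' @export
read_recording <- function(path, format = "raw-csv") {
  format <- match.arg(format, "raw-csv")
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, tz = "UTC")
  need <- c("timestamp", "x", "y", "z", "light", "temp")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  ts <- dt$timestamp
  if (!inherits(ts, "POSIXct")) ts <- acti_time(ts)
  if (anyNA(ts)) stop("data error: unparseable timestamps")
  secs <- as.numeric(ts)
  d <- diff(secs)
  if (any(d <= 0)) stop("data error: timestamps are not strictly increasing")
  fs <- 1 / median(d)
  # snap to an integer rate when within timestamp-precision jitter
  if (abs(fs - round(fs)) < 0.01) fs <- round(fs)
  new_triaxial_recording(start = ts[1], fs = fs, x = dt$x, y = dt$y, z = dt$z,
                         light = dt$light, temp = dt$temp, calibrated = FALSE)
}

#' Apply linear accelerometer calibration
#'
#' Per axis \code{a' = gain * a + offset} (gain applied first). Sensor output
#' is modelled as a linear function of true acceleration, so the
#' manufacturer-provided gain/offset invert the sensor transfer.
#'
#' @param rec uncalibrated triaxial_recording
#' @param params list with \code{offset} (3-vector, g) and \code{gain}
#'   (3-vector, dimensionless, no zero component)
#' @return calibrated triaxial_recording
#' @export
calibrate <- function(rec, params = list(offset = c(0, 0, 0), gain = c(1, 1, 1))) {
  if (isTRUE(rec$calibrated)) stop("recording is already calibrated")
  g <- params$gain; o <- params$offset
  if (length(g) != 3L || length(o) != 3L) stop("gain and offset must be 3-vectors")
  if (any(g == 0)) stop("parameter error: every gain component must be non-zero")
  rec$x <- g[1] * rec$x + o[1]
  rec$y <- g[2] * rec$y + o[2]
  rec$z <- g[3] * rec$z + o[3]
  if (max(abs(c(range(rec$x), range(rec$y), range(rec$z)))) > 8 + 1e-9) {
    warning("calibrated acceleration exceeds the +-8 g device dynamic range")
  }
  rec$calibrated <- TRUE
  rec
}

#' Resample a recording to 10 Hz by block averaging
#'
#' Each 10 Hz output sample is the mean of its non-overlapping block of
#' input samples (a crude anti-alias filter that is exactly testable).
#' Requires the input rate to be an integer multiple of 10 Hz; trailing
#' samples that do not fill a block are dropped.
#'
#' @param rec triaxial_recording with fs >= 10
#' @return triaxial_recording at 10 Hz
#' @export
resample_to_10hz <- function(rec) {
  if (rec$fs < 10) stop("unsupported: sampling rate below 10 Hz")
  k <- rec$fs / 10
  if (abs(k - round(k)) > 1e-9) stop("unsupported: sampling rate not an integer multiple of 10 Hz")
  k <- as.integer(round(k))
  if (k == 1L) return(rec)
  nb <- floor(n_samples(rec) / k)
  blockmean <- function(v) colMeans(matrix(v[seq_len(nb * k)], nrow = k))
  new_triaxial_recording(start = rec$start, fs = 10,
                         x = blockmean(rec$x), y = blockmean(rec$y),
                         z = blockmean(rec$z), light = blockmean(rec$light),
                         temp = blockmean(rec$temp), calibrated = rec$calibrated)
}

#' Detect non-wear periods from stillness plus sensor cooling
#'
#' A minute is non-wear-like when the device is simultaneously still (the
#' within-minute range of every acceleration axis is below
#' \code{stillness_eps}) and thermally off-body (mean wrist temperature
#' below \code{temp_threshold}, or falling faster than \code{temp_slope}
#' per minute). Maximal runs of such minutes shorter than
#' \code{min_duration} minutes are discarded: very short off-body episodes
#' are not reliably separable from quiet wear.
#'
#' @param rec calibrated triaxial_recording at 10 Hz
#' @param stillness_eps per-axis range threshold (g)
#' @param temp_threshold absolute temperature cut (degC)
#' @param temp_slope cooling-rate cut (degC/min, negative)
#' @param min_duration minimum episode length (minutes)
#' @return \code{\link{interval_set}} of non-wear episodes
#' @export
detect_nonwear <- function(rec, stillness_eps = 0.013, temp_threshold = 26,
                           temp_slope = -0.2, min_duration = 15) {
  if (!isTRUE(rec$calibrated)) stop("recording must be calibrated")
  spm <- as.integer(rec$fs * 60)
  n_min <- floor(n_samples(rec) / spm)
  if (n_min < min_duration) {
    warning("recording shorter than ", min_duration, " min; no nonwear detection")
    return(interval_set())
  }
  idx <- seq_len(n_min * spm)
  rng <- function(v) .block_range_c(v, spm, n_min)
  still <- rng(rec$x) < stillness_eps & rng(rec$y) < stillness_eps &
    rng(rec$z) < stillness_eps
  tm <- matrix(rec$temp[idx], nrow = spm)
  tmean <- colMeans(tm)
  # cooling rate from half-minute means: (second half - first half) / 0.5 min
  h <- spm %/% 2L
  slope <- (colMeans(tm[(h + 1L):spm, , drop = FALSE]) -
              colMeans(tm[1:h, , drop = FALSE])) / 0.5
  flag <- as.logical(still) & (tmean < temp_threshold | slope < temp_slope)
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  if (!any(keep)) return(interval_set())
  interval_set(rec$start + (starts[keep] - 1L) * 60,
               rec$start + ends[keep] * 60)
}
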