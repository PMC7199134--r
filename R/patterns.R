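# Day-level activity / sleep / circadian pattern extraction.
#
# Conventions: an activity day runs midnight to midnight (actogram
# convention); a sleep night runs noon to noon, so the main nocturnal sleep
# is never split. The diurnal window of day D is "rise time to bed time":
# from the main-sleep offset of the night ending on morning D to the
# main-sleep onset of the night starting on evening D.

#' The pattern registry: names in fixed emission order
#'
#' 50 named day-level patterns across activity, sleep and circadian rhythm.
#' @return character vector of pattern names
#' @export
pattern_registry <- function() {
  c("M10", "M10_time", "L5", "L5_time", "RA",
    "MDA", "MNA", "MA", "diurnal_skewness",
    "diurnal_p5", "diurnal_p25", "diurnal_p50", "diurnal_p75", "diurnal_p95",
    "pct_nocturnal_activity",
    "IS1", "IS2", "IV1", "IV2", "IV3",
    "tkeo_diurnal", "tkeo_ratio", "rmssd_diurnal", "rmssd_ratio",
    "cmse_5", "cmse_30", "cmse_60", "cmse_120",
    "sleep_onset", "sleep_offset", "sleep_duration",
    "n_wake_ups", "waso_minutes", "sleep_entropy",
    "sleep_p5", "sleep_p25", "sleep_p50", "sleep_p75", "sleep_p95",
    "awakenings_total_minutes",
    "temp_zenith", "temp_zenith_time", "temp_nadir", "temp_nadir_time",
    "temp_range",
    "onset_phase", "offset_phase",
    "cosinor_mesor", "cosinor_amplitude", "cosinor_phase")
}

hours_since_midnight <- function(t) {
  s <- as.numeric(t) %% 86400
  s / 3600
}

#' Nonparametric rest-activity rhythm metrics for one day
#'
#' M10 (L5) is the maximum (minimum) mean activity over all fully contained
#' 600-min (300-min) windows advanced by 1 min within the
#' midnight-to-midnight day; times are window start clock hours. The
#' relative amplitude RA = (M10 - L5) / (M10 + L5). Ties go to the earliest
#' window.
#'
#' @param day_values numeric vector of 1440 minute activity values (NA
#'   allowed)
#' @param max_missing maximum tolerated missing minutes (default 144, 10\%)
#' @return named list (M10, M10_time, L5, L5_time, RA); all NA when the day
#'   is too incomplete
#' @export
nonparametric_rhythm <- function(day_values, max_missing = 144) {
  nas <- list(M10 = NA_real_, M10_time = NA_real_, L5 = NA_real_,
              L5_time = NA_real_, RA = NA_real_)
  if (length(day_values) != 1440L) stop("day_values must have 1440 minutes")
  if (sum(is.na(day_values)) > max_missing) return(nas)
  wmean <- function(w) {
    k <- data.table::frollmean(day_values, w, na.rm = TRUE, align = "left")
    k[seq_len(1440 - w + 1)]
  }
  m10 <- wmean(600); l5 <- wmean(300)
  i10 <- which.max(m10); i5 <- which.min(l5)   # which.* take the earliest tie
  M10 <- m10[i10]; L5 <- l5[i5]
  list(M10 = M10, M10_time = (i10 - 1) / 60, L5 = L5, L5_time = (i5 - 1) / 60,
       RA = if ((M10 + L5) > 0) (M10 - L5) / (M10 + L5) else NA_real_)
}

#' Interday stability of the activity profile
#'
#' IS = (n * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2), computed
#' on hourly means: the x_i are the per-(day, bin) window means over the
#' whole recording, the xbar_h their clock-binned averages. IS1 uses 24
#' non-overlapping hourly bins; IS2 uses 48 one-hour bins advanced by 30
#' min. IS is 1 for a perfectly repeated 24-h profile and near
#' (p - 1) / n for structureless data. It is a recording-level quantity.
#'
#' @param values minute activity values for the whole recording, aligned so
#'   the first value is the first minute of a clock hour
#' @param start POSIXct start time of the first minute (defines clock
#'   alignment)
#' @param variant "IS1" or "IS2"
#' @return numeric; NA for a constant series
#' @export
interday_stability <- function(values, start, variant = c("IS1", "IS2")) {
  variant <- match.arg(variant)
  step <- if (variant == "IS1") 60L else 30L
  n_min <- length(values)
  if (n_min < 2L * 1440L) stop("interday stability needs at least 2 days")
  clock0 <- as.integer(round((as.numeric(acti_time(start)) %% 86400) / 60))
  # clock-periodic window construction: the recording is treated as circular
  # so every clock bin holds the same number of windows (one per day)
  xx <- c(values, values[seq_len(60L)])
  starts <- seq(1L, n_min, by = step)
  xi <- vapply(starts, function(s) mean(xx[s:(s + 59L)], na.rm = TRUE), 1)
  bins <- (((clock0 + starts - 1L) %% 1440L) %/% step)
  ok <- !is.nan(xi) & !is.na(xi)
  xi <- xi[ok]; bins <- bins[ok]
  if (length(xi) < 2L) return(NA_real_)
  xbar <- mean(xi)
  denom_core <- sum((xi - xbar)^2)
  if (denom_core == 0) return(NA_real_)
  bh <- tapply(xi, bins, mean)
  p <- length(bh); n <- length(xi)
  (n * sum((bh - xbar)^2)) / (p * denom_core)
}

#' Intraday variability of one day's activity
#'
#' IV = (N * sum (x_i - x_(i-1))^2) / ((N - 1) * sum (x_i - xbar)^2) at the
#' variant's resolution: IV1 on 24 hourly means, IV2 on the 1440 minute
#' values, IV3 on 47 one-hour means advanced by 30 min. IV is near 2 for
#' white noise and small for a smooth 24-h profile.
#'
#' @param day_values 1440 minute activity values (NA allowed)
#' @param variant "IV1", "IV2" or "IV3"
#' @return numeric; NA for a constant or too-sparse day
#' @export
intraday_variability <- function(day_values, variant = c("IV1", "IV2", "IV3")) {
  variant <- match.arg(variant)
  if (length(day_values) != 1440L) stop("day_values must have 1440 minutes")
  x <- switch(variant,
    IV1 = vapply(seq(1, 1440, by = 60), function(s) mean(day_values[s:(s + 59)], na.rm = TRUE), 1),
    IV2 = day_values,
    IV3 = vapply(seq(1, 1381, by = 30), function(s) mean(day_values[s:(s + 59)], na.rm = TRUE), 1))
  x <- x[!is.na(x) & !is.nan(x)]
  N <- length(x)
  if (N < 3L) return(NA_real_)
  denom <- sum((x - mean(x))^2)
  if (denom == 0) return(NA_real_)
  (N * sum(diff(x)^2)) / ((N - 1) * denom)
}

#' Teager-Kaiser energy features
#'
#' psi_n = x_n^2 - x_(n-1) x_(n+1), an instantaneous energy operator
#' sensitive to both amplitude and frequency of fluctuations.
#' \code{tkeo_diurnal} is the mean psi over the diurnal window;
#' \code{tkeo_ratio} relates it to the mean psi over the full 24-h day.
#'
#' @param day_values 1440 minute activity values
#' @param diurnal_idx integer indices (into day_values) of the diurnal
#'   window
#' @return list(tkeo_diurnal, tkeo_ratio)
#' @export
tkeo_features <- function(day_values, diurnal_idx) {
  psi_mean <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 3L) return(NA_real_)
    mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
  }
  td <- psi_mean(day_values[diurnal_idx])
  tf <- psi_mean(day_values)
  list(tkeo_diurnal = td,
       tkeo_ratio = if (!is.na(tf) && tf != 0) td / tf else NA_real_)
}

#' Root-mean-square of successive differences features
#'
#' rmssd = sqrt(mean (x_i - x_(i-1))^2) over the window; the ratio relates
#' the diurnal value to the full-24-h value.
#'
#' @inheritParams tkeo_features
#' @return list(rmssd_diurnal, rmssd_ratio)
#' @export
rmssd_features <- function(day_values, diurnal_idx) {
  rmssd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    sqrt(mean(diff(x)^2))
  }
  rd <- rmssd(day_values[diurnal_idx])
  rf <- rmssd(day_values)
  list(rmssd_diurnal = rd,
       rmssd_ratio = if (!is.na(rf) && rf != 0) rd / rf else NA_real_)
}

#' Sample entropy of a series
#'
#' SampEn(m, r): negative log of the conditional probability that sequences
#' matching for m points (Chebyshev distance <= r) also match for m + 1.
#' Self-matches are excluded. Returns NA when no template pair matches at
#' either length.
#'
#' @param x numeric series
#' @param m embedding dimension (default 2)
#' @param r tolerance on the original amplitude scale
#' @return numeric; 0 for a constant series
#' @export
sample_entropy <- function(x, m = 2L, r) {
  x <- x[!is.na(x)]
  N <- length(x)
  if (N < m + 2L) return(NA_real_)
  n_t <- N - m                       # same template count for both lengths
  count_matches <- function(mm) {
    d <- matrix(0, n_t, n_t)
    for (k in 0:(mm - 1L)) {
      v <- x[(1L + k):(n_t + k)]
      d <- pmax(d, abs(outer(v, v, "-")))
    }
    (sum(d <= r) - n_t) / 2          # unordered pairs, self-matches dropped
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Composite multiscale sample entropy of one day's activity
#'
#' For each scale tau the series is coarse-grained by non-overlapping block
#' means at every one of the tau possible offsets; sample entropy
#' (embedding \code{m}, tolerance \code{r_frac} times the SD of the
#' original minute series, fixed across scales) is computed on each grid
#' and averaged over the offsets where it is defined (the composite
#' variant, which stabilises entropy estimates on short coarse-grained
#' series).
#'
#' @param day_values 1440 minute activity values
#' @param scales coarse-graining scales in minutes
#' @param m embedding dimension
#' @param r_frac tolerance as a fraction of the scale-1 SD
#' @return named numeric vector, one entry per scale; NA where undefined
#' @export
cmse <- function(day_values, scales = c(5, 30, 60, 120), m = 2L, r_frac = 0.2) {
  x <- day_values
  r <- r_frac * sd(x, na.rm = TRUE)
  if (is.na(r)) r <- 0
  out <- setNames(numeric(length(scales)), paste0("cmse_", scales))
  for (si in seq_along(scales)) {
    tau <- scales[si]
    ents <- vapply(seq_len(tau), function(off) {
      xs <- x[off:length(x)]
      nb <- floor(length(xs) / tau)
      if (nb < m + 2L) return(NA_real_)
      cg <- colMeans(matrix(xs[seq_len(nb * tau)], nrow = tau))
      sample_entropy(cg, m, r)
    }, 1)
    out[si] <- if (all(is.na(ents))) NA_real_ else mean(ents, na.rm = TRUE)
  }
  out
}

#' Distribution features of diurnal and nocturnal activity
#'
#' MDA / MNA / MA are the mean movement over the diurnal window, the main
#' sleep window and the full day; skewness is the adjusted Fisher-Pearson
#' sample skewness of diurnal minutes; percentiles interpolate linearly
#' between order statistics; pct_nocturnal_activity is the ratio of summed
#' sleep-window movement to summed 24-h movement.
#'
#' @param day_values 1440 minute activity values
#' @param diurnal_idx indices of the diurnal window within the day
#' @param sleep_idx indices of the main sleep window within the day
#' @return named list
#' @export
distribution_features <- function(day_values, diurnal_idx, sleep_idx) {
  di <- day_values[diurnal_idx]; di <- di[!is.na(di)]
  ni <- day_values[sleep_idx]; ni <- ni[!is.na(ni)]
  all_v <- day_values[!is.na(day_values)]
  skew <- function(x) {
    n <- length(x)
    if (n < 3L || sd(x) == 0) return(NA_real_)
    m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
    sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
  }
  qs <- if (length(di)) quantile(di, c(.05, .25, .5, .75, .95), names = FALSE, type = 7)
        else rep(NA_real_, 5)
  tot <- sum(all_v)
  list(MDA = if (length(di)) mean(di) else NA_real_,
       MNA = if (length(ni)) mean(ni) else NA_real_,
       MA = if (length(all_v)) mean(all_v) else NA_real_,
       diurnal_skewness = skew(di),
       diurnal_p5 = qs[1], diurnal_p25 = qs[2], diurnal_p50 = qs[3],
       diurnal_p75 = qs[4], diurnal_p95 = qs[5],
       pct_nocturnal_activity = if (length(ni) && tot > 0) sum(ni) / tot else NA_real_)
}

#' Single-component cosinor fit of one day's activity
#'
#' Least-squares fit of x(t) = M + b1 cos(2 pi t / 24) + b2 sin(2 pi t /
#' 24) with t in clock hours. MESOR is M, amplitude sqrt(b1^2 + b2^2), and
#' the acrophase the clock time (hours in [0, 24)) at which the fitted
#' sinusoid peaks.
#'
#' @param day_values 1440 minute activity values
#' @param min_fraction minimum fraction of the day required (default 0.5)
#' @return list(mesor, amplitude, acrophase)
#' @export
cosinor_fit <- function(day_values, min_fraction = 0.5) {
  t_h <- (seq_along(day_values) - 1) / 60
  ok <- !is.na(day_values)
  if (mean(ok) < min_fraction) {
    return(list(mesor = NA_real_, amplitude = NA_real_, acrophase = NA_real_))
  }
  w <- 2 * pi / 24
  fit <- lm(day_values[ok] ~ cos(w * t_h[ok]) + sin(w * t_h[ok]))
  b <- coef(fit)
  amp <- sqrt(b[2]^2 + b[3]^2)
  phase <- (atan2(b[3], b[2]) / w) %% 24
  if (!is.finite(amp) || amp < 1e-12) {
    return(list(mesor = unname(b[1]), amplitude = 0, acrophase = NA_real_))
  }
  list(mesor = unname(b[1]), amplitude = unname(amp), acrophase = unname(phase))
}

#' Temperature extrema during one sleep window
#'
#' Maximum (zenith) and minimum (nadir) per-minute wrist temperature within
#' (onset, offset), their clock times in hours, and the range; non-wear
#' minutes are already missing in the temperature series. Ties go to the
#' earliest minute.
#'
#' @param temp temperature \code{\link{minute_series}}
#' @param record one main sleep record row
#' @param min_fraction minimum fraction of sleep minutes with temperature
#' @return named list
#' @export
temperature_sleep_features <- function(temp, record, min_fraction = 0.5) {
  nas <- list(temp_zenith = NA_real_, temp_zenith_time = NA_real_,
              temp_nadir = NA_real_, temp_nadir_time = NA_real_,
              temp_range = NA_real_)
  i0 <- as.integer(round(as.numeric(record$onset - temp$start, units = "mins"))) + 1L
  i1 <- as.integer(round(as.numeric(record$offset - temp$start, units = "mins")))
  i0 <- max(i0, 1L); i1 <- min(i1, length(temp))
  if (i1 < i0) return(nas)
  v <- temp$values[i0:i1]
  if (mean(!is.na(v)) < min_fraction || all(is.na(v))) return(nas)
  iz <- which.max(v); inad <- which.min(v)
  tt <- minute_times(temp)[i0:i1]
  list(temp_zenith = v[iz], temp_zenith_time = hours_since_midnight(tt[iz]),
       temp_nadir = v[inad], temp_nadir_time = hours_since_midnight(tt[inad]),
       temp_range = v[iz] - v[inad])
}

#' Night-to-night phase differences of sleep timing
#'
#' For night k, onset_phase is the difference between the clock time of
#' onset on night k and night k - 1, wrapped to (-12 h, +12 h], in minutes
#' (so 23:50 followed by 00:10 gives +20); likewise for offsets. The first
#' night (and any night lacking a neighbour) is missing.
#'
#' @param records sleep records; only main records are used
#' @return data.frame(night_id, onset_phase, offset_phase) in minutes
#' @export
phase_differences <- function(records) {
  main <- records[records$is_main, , drop = FALSE]
  main <- main[order(main$night_id), , drop = FALSE]
  wrap <- function(d) {                            # to (-720, 720]
    w <- ((d + 720) %% 1440) - 720
    ifelse(w == -720, 720, w)
  }
  clock_min <- function(t) (as.numeric(t) %% 86400) / 60
  n <- nrow(main)
  onset_phase <- offset_phase <- rep(NA_real_, n)
  if (n >= 2L) for (k in 2:n) {
    if (as.numeric(main$night_id[k] - main$night_id[k - 1]) == 1) {
      onset_phase[k] <- wrap(clock_min(main$onset[k]) - clock_min(main$onset[k - 1]))
      offset_phase[k] <- wrap(clock_min(main$offset[k]) - clock_min(main$offset[k - 1]))
    }
  }
  data.frame(night_id = main$night_id, onset_phase = onset_phase,
             offset_phase = offset_phase)
}
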