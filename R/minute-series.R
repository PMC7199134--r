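#' Per-minute scalar summary series
#'
#' The package's common container for minute-resolution summaries (movement,
#' xyz variation, light, temperature, detector masks): a start timestamp, a
#' fixed 60 s step, a numeric value vector and a missingness mask (typically
#' from non-wear). Missing minutes hold \code{NA} in \code{values}.
#'
#' @param start POSIXct start of the first minute.
#' @param values numeric (or logical) vector, one entry per minute.
#' @param missing logical mask, same length as \code{values}.
#' @return An object of class \code{minute_series}.
#' @export
minute_series <- function(start, values, missing = is.na(values)) {
  start <- acti_time(start)
  if (length(missing) != length(values)) stop("mask length must equal values length")
  values[missing] <- NA
  structure(list(start = start, step = 60, values = values,
                 missing = as.logical(missing)),
            class = "minute_series")
}

#' @export
length.minute_series <- function(x) length(x$values)

#' @export
print.minute_series <- function(x, ...) {
  cat(sprintf("<minute_series: %d min from %s, %d missing>\n",
              length(x), format(x$start), sum(x$missing)))
  invisible(x)
}

#' Timestamps of the minutes in a minute series
#' @param x minute_series
#' @return POSIXct vector (start of each minute)
#' @export
minute_times <- function(x) x$start + (seq_along(x$values) - 1) * 60

#' @export
as.data.frame.minute_series <- function(x, ...) {
  data.frame(timestamp = minute_times(x), value = x$values, missing = x$missing)
}

stopifnot_same_base <- function(...) {
  xs <- list(...)
  n <- vapply(xs, length, 1L)
  t0 <- vapply(xs, function(s) as.numeric(s$start), 1)
  if (length(unique(n)) != 1L || length(unique(t0)) != 1L) {
    stop("minute series do not share a time base")
  }
}

#' Rolling statistic over a minute series
#'
#' Windows containing more than 50\% missing values yield a missing value
#' (this keeps non-wear from leaking a numeric value into downstream rules);
#' otherwise the statistic is taken over the non-missing entries. Positions
#' where the window does not fully fit inside the series are missing.
#'
#' @param series minute_series
#' @param width_minutes window width (>= 1)
#' @param stat "mean" or "median"
#' @param align "right" (trailing, the default) or "center"
#' @return minute_series of the same length
#' @export
rolling_stat <- function(series, width_minutes, stat = c("mean", "median"),
                         align = c("right", "center")) {
  stat <- match.arg(stat)
  align <- match.arg(align)
  w <- as.integer(width_minutes)
  if (w < 1L) stop("width_minutes must be >= 1")
  x <- series$values
  n <- length(x)
  if (w > n) {
    warning("rolling window wider than the series; all values missing")
    return(minute_series(series$start, rep(NA_real_, n)))
  }
  out <- .roll_stat_c(as.numeric(x), w, stat == "median",
                      if (align == "center") 1L else 0L)
  minute_series(series$start, out)
}
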