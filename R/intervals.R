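#' Construct an ordered set of half-open time intervals
#'
#' An interval set is the package's container for non-wear episodes, sleep
#' windows and awakenings: a data frame with POSIXct columns \code{start} and
#' \code{end}, sorted by start, pairwise non-overlapping, with
#' \code{end > start} ([start, end) semantics).
#'
#' @param start,end POSIXct (or coercible) vectors of equal length.
#' @return An object of class \code{interval_set} (also a data.frame).
#' @export
interval_set <- function(start = as.POSIXct(character()), end = as.POSIXct(character())) {
  start <- acti_time(start)
  end <- acti_time(end)
  if (length(start) != length(end)) stop("start and end must have equal length")
  if (any(!(end > start))) stop("interval_set: every end must be after its start")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    stop("interval_set: intervals must be non-overlapping")
  }
  structure(data.frame(start = start, end = end),
            class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set: %d interval(s)>\n", nrow(x)))
  if (nrow(x)) print(data.frame(start = x$start, end = x$end,
                                minutes = as.numeric(x$end - x$start, units = "mins")))
  invisible(x)
}

#' Total duration of an interval set in minutes
#' @param x interval_set
#' @return numeric scalar (0 for an empty set)
#' @export
interval_minutes <- function(x) {
  if (!nrow(x)) return(0)
  sum(as.numeric(x$end - x$start, units = "mins"))
}

# Fraction of [start, start+60) minutes (indexed 1..n_min from `origin`)
# covered by any interval; returns numeric vector in [0, 1].
minute_overlap_fraction <- function(ivs, origin, n_min) {
  frac <- numeric(n_min)
  if (is.null(ivs) || !nrow(ivs)) return(frac)
  t0 <- as.numeric(acti_time(origin))
  for (i in seq_len(nrow(ivs))) {
    a <- as.numeric(ivs$start[i]); b <- as.numeric(ivs$end[i])
    lo <- max(1L, floor((a - t0) / 60) + 1L)
    hi <- min(n_min, ceiling((b - t0) / 60))
    if (hi < lo) next
    for (m in lo:hi) {
      ms <- t0 + (m - 1L) * 60; me <- ms + 60
      frac[m] <- frac[m] + (min(b, me) - max(a, ms)) / 60
    }
  }
  pmin(frac, 1)
}

# Logical mask: minute touched by any interval at all.
minutes_overlapping <- function(ivs, origin, n_min) {
  minute_overlap_fraction(ivs, origin, n_min) > 0
}

# Overlap in minutes between one [start,end) interval and an interval_set.
overlap_minutes <- function(start, end, ivs) {
  if (is.null(ivs) || !nrow(ivs)) return(0)
  a <- as.numeric(acti_time(start)); b <- as.numeric(acti_time(end))
  s <- pmax(as.numeric(ivs$start), a); e <- pmin(as.numeric(ivs$end), b)
  sum(pmax(e - s, 0)) / 60
}
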