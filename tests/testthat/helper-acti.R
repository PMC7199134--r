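# Shared helpers and lazily-built fixtures (everything generated in code).

t0 <- function(clock = "00:00:00", date = "2024-01-01") {
  as.POSIXct(paste(date, clock), tz = "UTC")
}

# Build a calibrated recording from per-sample channel vectors (recycled).
mk_rec <- function(n_min, fs = 10, x = 0, y = 0, z = 1, light = 0, temp = 31,
                   start = t0("12:00:00"), calibrated = TRUE) {
  n <- n_min * fs * 60
  actirhythm:::new_triaxial_recording(
    start = start, fs = fs,
    x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
    light = rep_len(light, n), temp = rep_len(temp, n),
    calibrated = calibrated)
}

ms <- function(values, start = t0()) minute_series(start, values)

# One shared 7-day default-condition simulation, built once per test run.
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- generate_recording(generator_config(days = 7, seed = 42))
  }
  .shared$sim
}
shared_bundle <- function() {
  if (is.null(.shared$bundle)) {
    .shared$bundle <- process_recording(shared_sim()$recording)
  }
  .shared$bundle
}
shared_days <- function() {
  if (is.null(.shared$days)) {
    .shared$days <- extract_all(shared_bundle())
  }
  .shared$days
}

# Naive reference implementations used as independent oracles.
naive_roll <- function(x, w, stat, align) {
  n <- length(x)
  out <- rep(NA_real_, n)
  f <- if (stat == "mean") mean else median
  for (i in seq_len(n - w + 1)) {
    win <- x[i:(i + w - 1)]
    pos <- if (align == "right") i + w - 1 else i + w %/% 2
    if (pos > n) next
    out[pos] <- if (mean(is.na(win)) > 0.5) NA_real_ else f(win, na.rm = TRUE)
  }
  out
}

naive_movement <- function(x, y, z, spm) {
  n_min <- floor(length(x) / spm)
  out <- numeric(n_min)
  for (m in seq_len(n_min)) {
    i <- ((m - 1) * spm + 1):(m * spm)
    out[m] <- sqrt(sum(diff(x[i])^2 + diff(y[i])^2 + diff(z[i])^2))
  }
  out
}

naive_sampen <- function(x, m, r) {
  N <- length(x)
  count <- function(mm) {
    tot <- 0L
    for (i in 1:(N - m)) for (j in 1:(N - m)) {   # N - m templates at both lengths
      if (i == j) next
      if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) tot <- tot + 1L
    }
    tot / 2
  }
  B <- count(m); A <- count(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}
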