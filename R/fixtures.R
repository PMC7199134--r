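# Synthetic wrist-recording generator. Emulates the signal properties the
# detector and the pattern registry rely on: nightly low-movement/low-light
# sleep with elevated wrist temperature, bursty intermittent daytime
# activity, intra-sleep awakenings (restlessness + a light switched on),
# optional naps, and non-wear episodes (stillness + cooling sensor).

.gen_defaults <- list(
  days = 7L,
  sampling_rate = 10,            # Hz; generated post-resampling by default
  sleep_onset_mean = "23:30",    # clock time of lights-out
  sleep_onset_sd = 30,           # minutes
  sleep_duration_mean = 8,       # hours
  sleep_duration_sd = 30,        # minutes
  awakening_rate = 1,            # expected awakenings / night (Poisson)
  awakening_duration_range = c(5, 25),  # minutes; must stay inside [1, 29]
  nap_probability = 0.1,         # per day
  nonwear_episodes = NULL,       # data.frame(start_hour, duration_min)
  wake_burst_intensity = 0.1,    # g; median lognormal burst amplitude
  sensor_noise_sd = 8e-4,        # g per sample; ~0.8 mg MEMS noise floor
  light_day_lux = 250,
  light_evening_lux = 80,
  sleep_temp_delta = 2,          # degC added to wrist temp during sleep
  seed = 1L
)

# Fixed internal constants of the simulated world (documented in the
# methods vignette; not part of the tunable surface).
.gen_const <- list(
  start_time = "2024-01-01 12:00:00",  # recordings start at noon
  base_temp = 31, ambient_temp = 22, nonwear_tau = 8,   # degC / minutes
  light_sleep_lux = 1, light_awakening_lux = 40,
  burst_prob = 0.7, posture_change_prob = 0.3,
  awakening_edge_margin = 45, awakening_gap = 35,       # minutes
  evening_start_min = 1200, evening_end_min = 420       # 20:00 .. 07:00
)

#' Configuration for the synthetic recording generator
#'
#' @param ... overrides of the default fields: \code{days},
#'   \code{sampling_rate} (Hz, 10 or an integer multiple of 10),
#'   \code{sleep_onset_mean} ("HH:MM" clock time), \code{sleep_onset_sd}
#'   (min), \code{sleep_duration_mean} (h), \code{sleep_duration_sd} (min),
#'   \code{awakening_rate} (per night), \code{awakening_duration_range}
#'   (min, within [1, 29] so every true awakening is joinable under the
#'   detector's 30-min gap rule), \code{nap_probability},
#'   \code{nonwear_episodes} (data.frame with \code{start_hour} from
#'   recording start and \code{duration_min}), \code{wake_burst_intensity}
#'   (g), \code{sensor_noise_sd} (g), \code{light_day_lux},
#'   \code{light_evening_lux}, \code{sleep_temp_delta} (degC), \code{seed}.
#' @return validated list of class \code{generator_config}
#' @export
generator_config <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.gen_defaults))
  if (length(bad)) stop("unknown generator_config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(.gen_defaults, over, keep.null = TRUE)
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(is.numeric(cfg$days), length(cfg$days) == 1L)
  if (cfg$days < 1) stop("generator_config: days must be >= 1")
  if (!(cfg$sampling_rate > 0)) stop("generator_config: sampling_rate must be > 0")
  if (cfg$sampling_rate %% 10 != 0) {
    stop("generator_config: sampling_rate must be 10 or an integer multiple of 10")
  }
  if (cfg$sleep_duration_mean < 2) {
    stop("generator_config: sleep_duration_mean must be >= 2 hours")
  }
  r <- cfg$awakening_duration_range
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1 || r[2] > 29) {
    stop("generator_config: awakening_duration_range must lie within [1, 29] minutes")
  }
  if (cfg$awakening_rate < 0) stop("generator_config: awakening_rate must be >= 0")
  if (cfg$sleep_onset_sd < 0 || cfg$sleep_duration_sd < 0 || cfg$sensor_noise_sd < 0) {
    stop("generator_config: standard deviations must be non-negative")
  }
  if (cfg$nap_probability < 0 || cfg$nap_probability > 1) {
    stop("generator_config: nap_probability must be in [0, 1]")
  }
  nw <- cfg$nonwear_episodes
  if (!is.null(nw)) {
    if (!is.data.frame(nw) || !all(c("start_hour", "duration_min") %in% names(nw))) {
      stop("generator_config: nonwear_episodes needs columns start_hour, duration_min")
    }
    if (any(nw$duration_min <= 0)) stop("generator_config: nonwear durations must be positive")
    if (any(nw$start_hour < 0) || any((nw$start_hour * 60 + nw$duration_min) > cfg$days * 1440)) {
      stop("generator_config: nonwear episodes must lie inside the recording")
    }
    o <- order(nw$start_hour)
    s <- nw$start_hour[o] * 60; e <- s + nw$duration_min[o]
    if (nrow(nw) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("generator_config: nonwear episodes must not overlap")
    }
  }
  invisible(cfg)
}

clock_to_min <- function(hhmm) {
  p <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

# Minute-level schedule: states 0 day-wake, 1 evening-wake, 2 sleep,
# 3 awakening, 4 nap, 5 nonwear. Drawn under the config seed.
.gen_schedule <- function(cfg) {
  n_min <- as.integer(cfg$days * 1440)
  start <- acti_time(.gen_const$start_time)
  onset_rel0 <- clock_to_min(cfg$sleep_onset_mean) - 720  # minutes after noon
  if (onset_rel0 < 0) onset_rel0 <- onset_rel0 + 1440
  sleep <- data.frame(night_id = as.Date(character()), onset_min = integer(),
                      offset_min = integer())
  awak <- data.frame(night_id = as.Date(character()), start_min = integer(),
                     end_min = integer())
  naps <- data.frame(start_min = integer(), end_min = integer())
  for (k in seq_len(cfg$days)) {
    base <- (k - 1L) * 1440L
    onset <- base + round(onset_rel0 + rnorm(1, 0, cfg$sleep_onset_sd))
    dur <- round(cfg$sleep_duration_mean * 60 + rnorm(1, 0, cfg$sleep_duration_sd))
    dur <- max(dur, 121L)
    offset <- min(onset + dur, base + 1440L - 30L)
    onset <- max(onset, base + 60L)
    night_date <- as.Date(start) + (k - 1L)
    sleep <- rbind(sleep, data.frame(night_id = night_date,
                                     onset_min = onset, offset_min = offset))
    # awakenings: kept clear of the sleep edges and of each other so every
    # true sleep fragment survives the detector's >=30-min segment rule
    n_a <- rpois(1, cfg$awakening_rate)
    placed <- matrix(numeric(0), ncol = 2)
    for (a in seq_len(n_a)) {
      d <- sample(seq(cfg$awakening_duration_range[1], cfg$awakening_duration_range[2]), 1)
      lo <- onset + .gen_const$awakening_edge_margin
      hi <- offset - .gen_const$awakening_edge_margin - d
      if (hi <= lo) next
      for (try in 1:100) {
        s <- round(runif(1, lo, hi)); e <- s + d
        ok <- !nrow(placed) || all(s >= placed[, 2] + .gen_const$awakening_gap |
                                   e <= placed[, 1] - .gen_const$awakening_gap)
        if (ok) { placed <- rbind(placed, c(s, e)); break }
      }
    }
    if (nrow(placed)) {
      placed <- placed[order(placed[, 1]), , drop = FALSE]
      awak <- rbind(awak, data.frame(night_id = night_date,
                                     start_min = placed[, 1], end_min = placed[, 2]))
    }
    # optional afternoon nap on the NEXT window's daytime (14:00-16:00)
    if (runif(1) < cfg$nap_probability && k < cfg$days) {
      ns <- base + 1440L + round(runif(1, 120, 180))  # 14:00-15:00 next day
      naps <- rbind(naps, data.frame(start_min = ns, end_min = ns + round(runif(1, 30, 60))))
    }
  }

  state <- integer(n_min)                # 0 = day wake
  clock <- ((seq_len(n_min) - 1L) + 720L) %% 1440L
  state[clock >= .gen_const$evening_start_min | clock < .gen_const$evening_end_min] <- 1L
  for (i in seq_len(nrow(sleep))) {
    state[(sleep$onset_min[i] + 1L):sleep$offset_min[i]] <- 2L
  }
  if (nrow(awak)) for (i in seq_len(nrow(awak))) {
    state[(awak$start_min[i] + 1L):awak$end_min[i]] <- 3L
  }
  if (nrow(naps)) for (i in seq_len(nrow(naps))) {
    state[(naps$start_min[i] + 1L):naps$end_min[i]] <- 4L
  }
  nw <- cfg$nonwear_episodes
  nonwear <- data.frame(start_min = integer(), end_min = integer())
  if (!is.null(nw) && nrow(nw)) {
    s <- round(nw$start_hour * 60); e <- s + round(nw$duration_min)
    nonwear <- data.frame(start_min = s, end_min = e)
    for (i in seq_len(nrow(nonwear))) {
      state[(nonwear$start_min[i] + 1L):nonwear$end_min[i]] <- 5L
    }
  }
  list(start = start, n_min = n_min, state = state,
       sleep = sleep, awak = awak, naps = naps, nonwear = nonwear)
}

#' Generate a synthetic wrist recording with ground truth
#'
#' Draws a seeded multi-day recording of triaxial acceleration (g), ambient
#' light (lux) and wrist temperature (degC), together with the exact sleep,
#' awakening, nap and non-wear intervals used to build it. Identical config
#' (including seed) yields identical output.
#'
#' @param config a \code{\link{generator_config}}
#' @return list with elements \code{recording} (a
#'   \code{triaxial_recording}, already in calibrated g units) and
#'   \code{truth} (list of interval tables; see Details).
#' @details \code{truth} holds \code{sleep} (night_id, onset, offset),
#'   \code{awakenings} (night_id, start, end), \code{naps} and
#'   \code{nonwear} (\code{\link{interval_set}}s) and \code{group} (NA unless
#'   set by \code{\link{generate_cohort}}).
#' @export
generate_recording <- function(config) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  validate_generator_config(config)
  withr::with_seed(config$seed, .generate_recording_impl(config))
}

.generate_recording_impl <- function(cfg) {
  sch <- .gen_schedule(cfg)
  n_min <- sch$n_min; state <- sch$state
  fs <- cfg$sampling_rate; spm <- as.integer(fs * 60)
  n <- n_min * spm
  K <- .gen_const

  # per-minute burst amplitude (g of extra per-sample noise)
  amp <- numeric(n_min)
  wake <- state %in% c(0L, 1L)
  on <- wake & runif(n_min) < K$burst_prob
  amp[on] <- rlnorm(sum(on), meanlog = log(cfg$wake_burst_intensity), sdlog = 0.5)
  awk <- state == 3L
  amp[awk] <- rlnorm(sum(awk), meanlog = log(cfg$wake_burst_intensity), sdlog = 0.5)

  # per-minute gravity orientation: changes on some active wake minutes
  change <- (amp > 0 & wake & runif(n_min) < K$posture_change_prob)
  change[1] <- TRUE
  idx <- cumsum(change)
  nch <- max(idx)
  v3 <- matrix(rnorm(3 * nch), ncol = 3)
  v3 <- v3 / sqrt(rowSums(v3^2))
  orient <- v3[idx, , drop = FALSE]

  sdm <- sqrt(cfg$sensor_noise_sd^2 + amp^2)
  sdm[state == 5L] <- 1e-5                       # device off-body: flatline
  sd_s <- rep(sdm, each = spm)
  acc <- lapply(1:3, function(j) {
    a <- rep(orient[, j], each = spm) + rnorm(n, 0, sd_s)
    pmin(pmax(a, -8), 8)                         # +-8 g dynamic range
  })

  lux_min <- numeric(n_min)
  lux_min[state == 0L] <- cfg$light_day_lux
  lux_min[state == 1L] <- cfg$light_evening_lux
  lux_min[state == 2L] <- K$light_sleep_lux
  lux_min[state == 3L] <- K$light_awakening_lux
  lux_min[state == 4L] <- cfg$light_day_lux      # nap in ambient daylight
  lux_min[state == 5L] <- cfg$light_day_lux
  light <- rep(lux_min, each = spm) * exp(rnorm(n, 0, 0.05))

  temp_min <- rep(K$base_temp, n_min)
  temp_min[state %in% c(2L, 3L)] <- K$base_temp + cfg$sleep_temp_delta
  temp_min <- as.numeric(stats::filter(temp_min, rep(1 / 10, 10), sides = 2))
  temp_min[is.na(temp_min)] <- K$base_temp
  temp <- rep(temp_min, each = spm)
  if (nrow(sch$nonwear)) for (i in seq_len(nrow(sch$nonwear))) {
    # continuous exponential cooling toward ambient at sample resolution
    s <- sch$nonwear$start_min[i] * spm + 1L
    e <- sch$nonwear$end_min[i] * spm
    t_enter <- temp[max(s - 1L, 1L)]
    el <- seq_len(e - s + 1L) / spm               # minutes into the episode
    temp[s:e] <- K$ambient_temp + (t_enter - K$ambient_temp) * exp(-el / K$nonwear_tau)
  }
  temp <- temp + rnorm(n, 0, 0.02)

  rec <- new_triaxial_recording(start = sch$start, fs = fs,
                                x = acc[[1]], y = acc[[2]], z = acc[[3]],
                                light = light, temp = temp, calibrated = TRUE)
  to_time <- function(m) sch$start + m * 60
  truth <- list(
    sleep = data.frame(night_id = sch$sleep$night_id,
                       onset = to_time(sch$sleep$onset_min),
                       offset = to_time(sch$sleep$offset_min)),
    awakenings = if (nrow(sch$awak)) {
      data.frame(night_id = sch$awak$night_id,
                 start = to_time(sch$awak$start_min),
                 end = to_time(sch$awak$end_min))
    } else data.frame(night_id = as.Date(character()),
                      start = acti_time(character()), end = acti_time(character())),
    naps = if (nrow(sch$naps)) interval_set(to_time(sch$naps$start_min),
                                            to_time(sch$naps$end_min)) else interval_set(),
    nonwear = if (nrow(sch$nonwear)) interval_set(to_time(sch$nonwear$start_min),
                                                  to_time(sch$nonwear$end_min)) else interval_set(),
    group = NA_character_
  )
  list(recording = rec, truth = truth)
}

#' Generate a two-group synthetic cohort
#'
#' Draws \code{n_per_group} participants per group. Group-specific config
#' deltas emulate a cohort contrast; the default \code{fragmented} group has
#' a higher awakening rate and more variable wake bursts than the controls,
#' and each participant gets an individual habitual bedtime/duration drawn
#' around the group config.
#'
#' @param n_per_group participants per group (>= 1)
#' @param group_effects named list: per-group list of
#'   \code{\link{generator_config}} overrides. Default: \code{control} (no
#'   deltas) and \code{fragmented} (awakening_rate 2.5, wake_burst_intensity
#'   0.15).
#' @param seed integer master seed
#' @param base_config shared config overrides applied to every participant
#' @return list of participants, each \code{list(recording, truth, label, id)}
#' @export
generate_cohort <- function(n_per_group,
                            group_effects = list(
                              control = list(),
                              fragmented = list(awakening_rate = 2.5,
                                                wake_burst_intensity = 0.15)),
                            seed = 1L, base_config = list()) {
  plan <- cohort_plan(n_per_group, group_effects, seed, base_config)
  lapply(plan, function(p) {
    sim <- generate_recording(p$config)
    sim$truth$group <- p$label
    list(recording = sim$recording, truth = sim$truth, label = p$label, id = p$id)
  })
}

#' Plan a synthetic cohort without generating the recordings
#'
#' Returns the per-participant generator configs (with individual habitual
#' bedtime/duration shifts and derived seeds) so large cohorts can be
#' generated and processed one participant at a time within bounded memory.
#'
#' @inheritParams generate_cohort
#' @return list of \code{list(id, label, config)}
#' @export
cohort_plan <- function(n_per_group,
                        group_effects = list(
                          control = list(),
                          fragmented = list(awakening_rate = 2.5,
                                            wake_burst_intensity = 0.15)),
                        seed = 1L, base_config = list()) {
  if (!is.list(group_effects) || !length(group_effects) || is.null(names(group_effects))) {
    stop("group_effects must be a non-empty named list")
  }
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  out <- list(); pid <- 0L
  onset0 <- clock_to_min(.gen_defaults$sleep_onset_mean)
  for (g in names(group_effects)) {
    for (i in seq_len(n_per_group)) {
      pid <- pid + 1L
      pseed <- as.integer((as.numeric(seed) * 131 + pid * 7919) %% 2147483629)
      indiv <- withr::with_seed(pseed + 1L, list(
        onset_shift = rnorm(1, 0, 20),              # habitual bedtime shift, min
        dur_shift = rnorm(1, 0, 20)))               # habitual duration shift, min
      over <- utils::modifyList(base_config, group_effects[[g]], keep.null = TRUE)
      om <- if (!is.null(over$sleep_onset_mean)) clock_to_min(over$sleep_onset_mean) else onset0
      om <- (om + round(indiv$onset_shift)) %% 1440
      over$sleep_onset_mean <- sprintf("%02d:%02d", om %/% 60, om %% 60)
      dm <- if (!is.null(over$sleep_duration_mean)) over$sleep_duration_mean else .gen_defaults$sleep_duration_mean
      over$sleep_duration_mean <- max(2, dm + indiv$dur_shift / 60)
      over$seed <- pseed
      out[[pid]] <- list(id = sprintf("P%03d", pid), label = g,
                         config = do.call(generator_config, over))
    }
  }
  out
}

#' Simulate a per-night sleep diary from ground truth
#'
#' One row per night with the true onset/offset perturbed by Gaussian
#' reporting noise and the true awakening count. \code{report_noise_sd = 0}
#' reproduces the truth exactly.
#'
#' @param truth ground-truth list from \code{\link{generate_recording}}
#' @param report_noise_sd reporting noise SD in minutes
#' @param seed integer seed for the reporting noise
#' @return data.frame(night_id, onset, offset, n_awakenings)
#' @export
write_diary <- function(truth, report_noise_sd = 0, seed = 1L) {
  if (!nrow(truth$sleep)) stop("truth must contain at least one night")
  withr::with_seed(seed, {
    n <- nrow(truth$sleep)
    onset <- truth$sleep$onset + round(rnorm(n, 0, report_noise_sd)) * 60
    offset <- truth$sleep$offset + round(rnorm(n, 0, report_noise_sd)) * 60
    counts <- vapply(truth$sleep$night_id, function(d) {
      sum(truth$awakenings$night_id == d)
    }, 1L)
    data.frame(night_id = truth$sleep$night_id, onset = onset, offset = offset,
               n_awakenings = counts)
  })
}
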