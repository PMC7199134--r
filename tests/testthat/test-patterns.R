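test_that("M10/L5/RA limits and exhaustive-scan oracle", {
  const <- rep(2, 1440)
  r <- nonparametric_rhythm(const)
  expect_equal(r$M10, 2); expect_equal(r$L5, 2); expect_equal(r$RA, 0)
  # a single 10-h active block starting 08:00
  x <- rep(0, 1440); x[(8 * 60 + 1):(18 * 60)] <- 1
  r2 <- nonparametric_rhythm(x)
  expect_equal(r2$M10, 1); expect_equal(r2$L5, 0); expect_equal(r2$RA, 1)
  expect_equal(r2$M10_time, 8)
  for (rep in 1:5) {
    withr::with_seed(300 + rep, { x <- runif(1440) })
    got <- nonparametric_rhythm(x)
    m10 <- vapply(1:841, function(s) mean(x[s:(s + 599)]), 1)
    l5 <- vapply(1:1141, function(s) mean(x[s:(s + 299)]), 1)
    expect_equal(got$M10, max(m10), tolerance = 1e-9)
    expect_equal(got$L5, min(l5), tolerance = 1e-9)
    expect_equal(got$M10_time, (which.max(m10) - 1) / 60, tolerance = 1e-9)
    expect_equal(got$RA, (max(m10) - min(l5)) / (max(m10) + min(l5)), tolerance = 1e-9)
  }
  expect_true(is.na(nonparametric_rhythm(rep(NA_real_, 1440))$M10))
})

test_that("interday stability is 1 for identical repeated days and matches a binned oracle", {
  withr::with_seed(41, { prof <- runif(1440) })
  series <- rep(prof, 7)
  expect_equal(interday_stability(series, t0(), "IS1"), 1, tolerance = 1e-9)
  expect_equal(interday_stability(series, t0(), "IS2"), 1, tolerance = 1e-9)
  expect_true(is.na(interday_stability(rep(3, 1440 * 3), t0(), "IS1")))
  # oracle: explicit hourly means + clock bins on 3 random days
  withr::with_seed(42, { x <- runif(1440 * 3) })
  got <- interday_stability(x, t0(), "IS1")
  xi <- vapply(seq(1, length(x) - 59, by = 60), function(s) mean(x[s:(s + 59)]), 1)
  bins <- rep(0:23, 3)
  xb <- mean(xi)
  o <- (length(xi) * sum((tapply(xi, bins, mean) - xb)^2)) /
    (24 * sum((xi - xb)^2))
  expect_equal(got, o, tolerance = 1e-9)
})

test_that("IS is assigned recording-wide and is unaffected by a day-level scale change", {
  # scale equivariance: IS is a ratio, multiplying the series by c leaves it fixed
  withr::with_seed(43, { x <- runif(1440 * 4) })
  expect_equal(interday_stability(5 * x, t0(), "IS2"),
               interday_stability(x, t0(), "IS2"), tolerance = 1e-12)
})

test_that("intraday variability: closed-form limits and loop oracle", {
  # smooth 24-h sinusoid sampled hourly has tiny successive differences
  tt <- (0:1439) / 60
  sinus <- 2 + sin(2 * pi * tt / 24)
  expect_lt(intraday_variability(sinus, "IV1"), 0.3)
  for (rep in 1:5) {
    withr::with_seed(310 + rep, { x <- rnorm(1440) })
    for (v in c("IV1", "IV2", "IV3")) {
      xs <- switch(v,
        IV1 = vapply(seq(1, 1440, 60), function(s) mean(x[s:(s + 59)]), 1),
        IV2 = x,
        IV3 = vapply(seq(1, 1381, 30), function(s) mean(x[s:(s + 59)]), 1))
      o <- (length(xs) * sum(diff(xs)^2)) /
        ((length(xs) - 1) * sum((xs - mean(xs))^2))
      expect_equal(intraday_variability(x, v), o, tolerance = 1e-9)
    }
  }
  expect_true(is.na(intraday_variability(rep(1, 1440), "IV2")))
})

test_that("TKEO: constants vanish, ramps give one, sinusoids give the closed form", {
  idx <- 1:500
  expect_equal(tkeo_features(rep(3, 1440), idx)$tkeo_diurnal, 0)
  ramp <- seq_len(1440)
  expect_equal(tkeo_features(ramp, idx)$tkeo_diurnal, 1)   # n^2 - (n-1)(n+1) = 1
  A <- 2; om <- 0.3
  x <- A * sin(om * (1:1440))
  expect_equal(tkeo_features(x, 1:1440)$tkeo_diurnal, A^2 * sin(om)^2,
               tolerance = 1e-8)    # psi of a pure sinusoid is constant
})

test_that("RMSSD features match brute force and the ratio is diurnal over full day", {
  expect_equal(rmssd_features(rep(2, 100), 1:50)$rmssd_diurnal, 0)
  expect_equal(rmssd_features(rep(c(0, 1), 720), 1:1440)$rmssd_diurnal, 1)
  withr::with_seed(44, { x <- rnorm(1440) })
  idx <- 200:900
  got <- rmssd_features(x, idx)
  expect_equal(got$rmssd_diurnal, sqrt(mean(diff(x[idx])^2)), tolerance = 1e-12)
  expect_equal(got$rmssd_ratio,
               sqrt(mean(diff(x[idx])^2)) / sqrt(mean(diff(x)^2)), tolerance = 1e-12)
})

test_that("sample entropy agrees with a naive counting oracle and handles constants", {
  expect_equal(sample_entropy(rep(5, 100), 2, 0), 0)
  for (rep in 1:5) {
    withr::with_seed(320 + rep, { x <- rnorm(60) })
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, 2, r), naive_sampen(x, 2, r), tolerance = 1e-9)
  }
})

test_that("composite multiscale entropy: constants, offset averaging, noise ordering", {
  expect_equal(unname(cmse(rep(1, 1440))), rep(0, 4))
  # tau = 5 equals the average of naive per-offset sample entropies
  withr::with_seed(45, { x <- rnorm(300) })
  r <- 0.2 * sd(x)
  got <- cmse(x, scales = 5)
  ents <- vapply(1:5, function(off) {
    xs <- x[off:300]
    nb <- floor(length(xs) / 5)
    naive_sampen(colMeans(matrix(xs[1:(nb * 5)], nrow = 5)), 2, r)
  }, 1)
  expect_equal(unname(got), mean(ents, na.rm = TRUE), tolerance = 1e-9)
  # coarse-graining i.i.d. noise with a fixed tolerance lowers entropy
  withr::with_seed(46, {
    mat <- replicate(50, cmse(rnorm(1440)))
  })
  means <- rowMeans(mat, na.rm = TRUE)
  expect_true(all(diff(means) <= 1e-9))
})

test_that("distribution features: symmetry, zero nocturnal ratio, interpolated percentiles", {
  sym <- c(-2, -1, 0, 1, 2)
  d <- rep(0, 1440); d[101:105] <- sym
  f <- distribution_features(d, 101:105, 1:50)
  expect_equal(f$diurnal_skewness, 0)
  expect_equal(f$MNA, 0)
  # zero movement during sleep, positive by day -> nocturnal share 0
  dpos <- rep(0, 1440); dpos[400:900] <- 1
  fpos <- distribution_features(dpos, 400:900, 1:50)
  expect_equal(fpos$pct_nocturnal_activity, 0)
  # percentiles of 1..100 under linear order-statistic interpolation
  d2 <- rep(NA_real_, 1440); d2[1:100] <- sample(1:100)
  f2 <- distribution_features(d2, 1:100, integer(0))
  expect_equal(f2$diurnal_p25, 25.75)
  expect_equal(f2$diurnal_p5, unname(quantile(1:100, 0.05)))
  withr::with_seed(47, { v <- runif(500) })
  d3 <- rep(NA_real_, 1440); d3[1:500] <- v
  f3 <- distribution_features(d3, 1:500, integer(0))
  sv <- sort(v)
  expect_equal(f3$diurnal_p50, unname(quantile(sv, 0.5)), tolerance = 1e-12)
  expect_true(f3$diurnal_p5 <= f3$diurnal_p25 && f3$diurnal_p25 <= f3$diurnal_p50 &&
              f3$diurnal_p50 <= f3$diurnal_p75 && f3$diurnal_p75 <= f3$diurnal_p95)
})

test_that("cosinor fit recovers a noiseless 24-h cosine exactly", {
  tt <- (0:1439) / 60
  x <- 2 + 1.5 * cos(2 * pi * (tt - 14) / 24)
  f <- cosinor_fit(x)
  expect_equal(f$mesor, 2, tolerance = 1e-8)
  expect_equal(f$amplitude, 1.5, tolerance = 1e-8)
  expect_equal(f$acrophase, 14, tolerance = 1e-8)
  fc <- cosinor_fit(rep(3, 1440))
  expect_equal(fc$mesor, 3)
  expect_equal(fc$amplitude, 0)
  expect_true(is.na(fc$acrophase))
  # shift invariance of phase; mesor shifts by the constant
  f2 <- cosinor_fit(x + 10)
  expect_equal(f2$mesor, 12, tolerance = 1e-8)
  expect_equal(f2$acrophase, f$acrophase, tolerance = 1e-8)
  expect_true(is.na(cosinor_fit(c(x[1:500], rep(NA, 940)))$mesor))
})

test_that("temperature sleep features find extrema and their clock times", {
  tp <- ms(rep(34, 600), start = t0("22:00:00"))
  rec <- data.frame(onset = t0("23:00:00"), offset = t0("06:00:00", "2024-01-02"))
  f <- temperature_sleep_features(tp, rec)
  expect_equal(f$temp_zenith, 34); expect_equal(f$temp_nadir, 34)
  expect_equal(f$temp_range, 0)
  v <- rep(33, 600); v[120] <- 35.5                      # minute 120 ~ 23:59
  f2 <- temperature_sleep_features(ms(v, start = t0("22:00:00")), rec)
  expect_equal(f2$temp_zenith, 35.5)
  expect_equal(f2$temp_zenith_time, 23 + 59 / 60, tolerance = 1e-9)
  withr::with_seed(48, { v3 <- runif(600, 30, 36) })
  f3 <- temperature_sleep_features(ms(v3, start = t0("22:00:00")), rec)
  win <- v3[61:480]                                       # 23:00 .. 06:00
  expect_equal(f3$temp_zenith, max(win))
  expect_equal(f3$temp_nadir, min(win))
  expect_true(is.na(temperature_sleep_features(ms(rep(NA_real_, 600),
                                                  start = t0("22:00:00")), rec)$temp_zenith))
})

test_that("phase differences wrap across midnight and skip gaps", {
  sr <- data.frame(
    night_id = as.Date("2024-01-01") + 0:3,
    onset = c(t0("23:50:00"), t0("00:10:00", "2024-01-03"),
              t0("00:10:00", "2024-01-04"), t0("23:40:00", "2024-01-04")),
    offset = c(t0("07:00:00", "2024-01-02"), t0("07:30:00", "2024-01-03"),
               t0("07:30:00", "2024-01-04"), t0("07:00:00", "2024-01-05")),
    is_main = TRUE)
  ph <- phase_differences(sr)
  expect_true(is.na(ph$onset_phase[1]))
  expect_equal(ph$onset_phase[2], 20)     # 23:50 -> 00:10 wraps to +20
  expect_equal(ph$onset_phase[3], 0)
  expect_equal(ph$onset_phase[4], -30)
  expect_equal(ph$offset_phase[2], 30)
  # a missing neighbour night leaves NA
  sr2 <- sr[c(1, 3), ]
  expect_true(all(is.na(phase_differences(sr2)$onset_phase)))
})

test_that("pattern registry is stable: 50 unique names in documented order", {
  reg <- pattern_registry()
  expect_length(reg, 50)
  expect_false(any(duplicated(reg)))
  defs <- pattern_definitions()
  expect_identical(defs$name, reg)
  expect_false(any(is.na(defs$description)))
  # frozen order: first and last entries pin the snapshot
  expect_identical(reg[1:5], c("M10", "M10_time", "L5", "L5_time", "RA"))
  expect_identical(reg[48:50], c("cosinor_mesor", "cosinor_amplitude", "cosinor_phase"))
})

test_that("extract_all emits one row per complete civil day with the registry columns", {
  days <- shared_days()
  expect_equal(nrow(days), 6)              # 7 nights from noon -> 6 full civil days
  expect_identical(names(days), c("date", "valid", pattern_registry()))
  expect_true(all(days$valid))
  ok <- days
  expect_true(all(ok$RA >= 0 & ok$RA <= 1, na.rm = TRUE))
  expect_true(all(ok$pct_nocturnal_activity >= 0 & ok$pct_nocturnal_activity <= 1,
                  na.rm = TRUE))
  expect_true(all(ok$temp_range >= 0, na.rm = TRUE))
  expect_true(all(ok$cosinor_amplitude >= 0, na.rm = TRUE))
  expect_true(all(ok$cosinor_phase >= 0 & ok$cosinor_phase < 24, na.rm = TRUE))
  expect_true(all(ok$diurnal_p5 <= ok$diurnal_p25 & ok$diurnal_p25 <= ok$diurnal_p50 &
                  ok$diurnal_p50 <= ok$diurnal_p75 & ok$diurnal_p75 <= ok$diurnal_p95,
                  na.rm = TRUE))
  # IS replicated across the participant's days
  expect_equal(length(unique(ok$IS1)), 1)
})

test_that("a day dominated by non-wear is flagged invalid", {
  sim <- generate_recording(generator_config(
    days = 2, seed = 15, nap_probability = 0,
    nonwear_episodes = data.frame(start_hour = 13, duration_min = 9 * 60)))
  b <- process_recording(sim$recording, nonwear = sim$truth$nonwear)
  days <- suppressWarnings(extract_all(b))
  expect_false(days$valid[1])
  expect_true(all(is.na(days[1, pattern_registry()])))
})

test_that("scale equivariance and shift behaviour of the day-level metrics", {
  withr::with_seed(49, { x <- runif(1440, 0, 2) })
  c0 <- 3.7
  np1 <- nonparametric_rhythm(x); np2 <- nonparametric_rhythm(c0 * x)
  expect_equal(np2$M10, c0 * np1$M10, tolerance = 1e-9)
  expect_equal(np2$L5, c0 * np1$L5, tolerance = 1e-9)
  expect_equal(np2$RA, np1$RA, tolerance = 1e-9)
  expect_equal(intraday_variability(c0 * x, "IV2"), intraday_variability(x, "IV2"),
               tolerance = 1e-12)
  expect_equal(intraday_variability(x + c0, "IV2"), intraday_variability(x, "IV2"),
               tolerance = 1e-9)
  f1 <- cosinor_fit(x); f2 <- cosinor_fit(c0 * x)
  expect_equal(f2$amplitude, c0 * f1$amplitude, tolerance = 1e-9)
  expect_equal(f2$mesor, c0 * f1$mesor, tolerance = 1e-9)
  sk1 <- distribution_features(x, 1:720, 721:1440)
  sk2 <- distribution_features(c0 * x, 1:720, 721:1440)
  expect_equal(sk2$diurnal_skewness, sk1$diurnal_skewness, tolerance = 1e-9)
  expect_equal(sk2$MDA, c0 * sk1$MDA, tolerance = 1e-12)
  expect_equal(sk2$pct_nocturnal_activity, sk1$pct_nocturnal_activity, tolerance = 1e-12)
  r1 <- rmssd_features(x, 1:720); r2 <- rmssd_features(c0 * x, 1:720)
  expect_equal(r2$rmssd_diurnal, c0 * r1$rmssd_diurnal, tolerance = 1e-12)
})

test_that("participant summaries aggregate day patterns with mean and sample SD", {
  days <- shared_days()
  s <- summarize_participant(days)
  expect_equal(s$n_valid_days, sum(days$valid))
  expect_equal(unname(s$mean["IV2"]), mean(days$IV2[days$valid]))
  # constructed two-day table: {1, 3} -> mean 2, SD sqrt(2)
  fake <- days[1:2, ]
  fake$M10 <- c(1, 3)
  s2 <- summarize_participant(fake)
  expect_equal(unname(s2$mean["M10"]), 2)
  expect_equal(unname(s2$sd["M10"]), sqrt(2))
  # identical days -> SD 0
  fake2 <- days[c(1, 1), ]
  s3 <- summarize_participant(fake2)
  expect_true(all(s3$sd == 0, na.rm = TRUE))
  expect_error(summarize_participant(days[days$valid == FALSE, ]), "no valid day")
})
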