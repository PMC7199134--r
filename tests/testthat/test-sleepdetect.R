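mask_of <- function(cand) minute_series(t0(), cand, missing = rep(FALSE, length(cand)))

test_that("threshold container validates its invariants", {
  thr <- detector_thresholds()
  expect_equal(thr$movement_max, 0.07)
  expect_equal(thr$light_max, 30)
  expect_error(detector_thresholds(movement_max = 0), "positive")
  expect_error(detector_thresholds(min_sleep = 20, min_segment = 30), "min_sleep")
})

test_that("candidate rules are strict and jointly required", {
  n <- 60
  zero <- ms(rep(0, n))
  dark <- ms(rep(0, n))
  cand <- sleep_candidates(zero, zero, dark)
  expect_true(all(cand$values[6:(n - 5)]))            # all candidates after warm-up
  # constant light at 100 lux vetoes everything despite zero activity
  bright <- ms(rep(100, n))
  expect_false(any(sleep_candidates(zero, zero, bright)$values))
  # rolling median movement exactly at 0.07 is NOT below the threshold
  at_thr <- ms(rep(0.07, n))
  expect_false(any(sleep_candidates(at_thr, zero, dark)$values))
  just_below <- ms(rep(0.07 - 1e-9, n))
  expect_true(any(sleep_candidates(just_below, zero, dark)$values))
  # missing inputs are never candidates
  gap <- rep(0, n); gap[20:40] <- NA
  expect_false(any(sleep_candidates(ms(gap), zero, dark)$values[26:34]))
  expect_error(sleep_candidates(zero, ms(rep(0, n + 1)), dark), "time base")
})

test_that("two-rule mode without light warns loudly", {
  n <- 30
  zero <- ms(rep(0, n))
  expect_warning(cand <- sleep_candidates(zero, zero, NULL, use_light = FALSE),
                 "light")
  expect_true(any(cand$values))
})

test_that("merging follows the segment, gap and 2-hour span rules exactly", {
  thr <- detector_thresholds()
  runs <- function(...) {
    spec <- list(...)
    unlist(lapply(spec, function(s) rep(s[1] == 1, s[2])))
  }
  # 40 T + 20 F + 40 T: span 100 min < 120 -> removed
  b <- merge_candidates(mask_of(runs(c(1, 40), c(0, 20), c(1, 40))), thr)
  expect_equal(nrow(b), 0)
  # 40 T + 20 F + 80 T: span 140 retained with one 20-min awakening
  b <- merge_candidates(mask_of(runs(c(1, 40), c(0, 20), c(1, 80))), thr)
  expect_equal(nrow(b), 1)
  expect_equal(as.numeric(b$offset - b$onset, units = "mins"), 140)
  expect_equal(b$n_awakenings, 1)
  expect_equal(interval_minutes(b$awakenings[[1]]), 20)
  expect_equal(as.numeric(b$awakenings[[1]]$start - t0(), units = "mins"), 40)
  # isolated 90-min run -> removed (less than 2 hours)
  b <- merge_candidates(mask_of(runs(c(0, 10), c(1, 90), c(0, 10))), thr)
  expect_equal(nrow(b), 0)
  # a 25-min run 10 min before a 3-h run is never joined (run < 30 min)
  b <- merge_candidates(mask_of(runs(c(1, 25), c(0, 10), c(1, 180))), thr)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_awakenings, 0)
  expect_equal(as.numeric(b$onset - t0(), units = "mins"), 35)
  # a 31-min gap is an independent block boundary, not an awakening
  b <- merge_candidates(mask_of(runs(c(1, 130), c(0, 31), c(1, 130))), thr)
  expect_equal(nrow(b), 2)
  expect_true(all(b$n_awakenings == 0))
})

test_that("merging is idempotent", {
  thr <- detector_thresholds()
  withr::with_seed(30, {
    cand <- runif(1000) < 0.6
  })
  b1 <- merge_candidates(mask_of(cand), thr)
  # re-express the merged result as a mask: block minutes minus awakenings
  cand2 <- rep(FALSE, 1000)
  for (i in seq_len(nrow(b1))) {
    i0 <- as.numeric(b1$onset[i] - t0(), units = "mins") + 1
    i1 <- as.numeric(b1$offset[i] - t0(), units = "mins")
    cand2[i0:i1] <- TRUE
    aw <- b1$awakenings[[i]]
    for (j in seq_len(nrow(aw))) {
      a0 <- as.numeric(aw$start[j] - t0(), units = "mins") + 1
      a1 <- as.numeric(aw$end[j] - t0(), units = "mins")
      cand2[a0:a1] <- FALSE
    }
  }
  b2 <- merge_candidates(mask_of(cand2), thr)
  expect_equal(b2$onset, b1$onset)
  expect_equal(b2$offset, b1$offset)
  expect_equal(b2$n_awakenings, b1$n_awakenings)
})

test_that("raising the light threshold only grows the candidate set", {
  n <- 200
  withr::with_seed(31, {
    mv <- ms(abs(rnorm(n, 0.05, 0.03)))
    xv <- ms(abs(rnorm(n, 0.05, 0.05)))
    lt <- ms(runif(n, 0, 60))
  })
  lo <- sleep_candidates(mv, xv, lt, detector_thresholds(light_max = 30))$values
  hi <- sleep_candidates(mv, xv, lt, detector_thresholds(light_max = 50))$values
  expect_true(all(hi[lo]))
})

test_that("night assignment picks the longest block per noon-to-noon window, earliest on ties", {
  blocks <- data.frame(
    onset = c(t0("14:00:00"), t0("23:00:00")),
    offset = c(t0("16:30:00"), t0("07:00:00", "2024-01-02")),
    n_awakenings = c(0L, 0L))
  blocks$awakenings <- list(interval_set(), interval_set())
  sr <- assign_nights(blocks, t0("12:00:00"), t0("12:00:00", "2024-01-02"))
  expect_equal(sr$is_main, c(FALSE, TRUE))
  expect_equal(unique(sr$night_id), as.Date("2024-01-01"))
  # tie in span -> earlier onset wins
  tie <- data.frame(
    onset = c(t0("22:00:00"), t0("02:00:00", "2024-01-02")),
    offset = c(t0("01:00:00", "2024-01-02"), t0("05:00:00", "2024-01-02")),
    n_awakenings = c(0L, 0L))
  tie$awakenings <- list(interval_set(), interval_set())
  sr2 <- assign_nights(tie, t0("12:00:00"), t0("12:00:00", "2024-01-02"))
  expect_equal(sr2$is_main, c(TRUE, FALSE))
  # empty window reported missing
  sr3 <- assign_nights(blocks, t0("12:00:00"), t0("12:00:00", "2024-01-03"))
  expect_equal(attr(sr3, "missing_nights"), as.Date("2024-01-02"))
})

test_that("sleep metrics: counts, totals, entropy limits and percentiles", {
  n <- 600
  mv <- ms(rep(0, n))
  rec <- data.frame(onset = t0() + 60 * 60, offset = t0() + 60 * 360)  # 5 h
  rec$awakenings <- list(interval_set())
  m <- sleep_metrics(rec, mv)
  expect_equal(m$number_wake_ups, 0)
  expect_equal(m$awakenings_total_minutes, 0)
  expect_equal(m$waso_minutes, 0)
  expect_equal(m$sleep_entropy, 0)          # single occupied histogram bin
  expect_equal(m$duration_min, 300)
  # one 20-min awakening
  rec2 <- rec
  rec2$awakenings <- list(interval_set(t0() + 60 * 120, t0() + 60 * 140))
  expect_equal(sleep_metrics(rec2, mv)$awakenings_total_minutes, 20)
  expect_equal(sleep_metrics(rec2, mv)$number_wake_ups, 1)
  # entropy of movement uniform over k occupied bins is ln k
  vals <- rep(c(0.02, 0.12, 0.22, 0.32), each = 75)   # 4 bins, equal mass
  mv3 <- ms(rep(c(vals, rep(0, n - 300)), length.out = n))
  mv3$values[61:360] <- rep(c(0.02, 0.12, 0.22, 0.32), each = 75)
  m3 <- sleep_metrics(rec, mv3)
  expect_equal(m3$sleep_entropy, log(4), tolerance = 1e-12)
  expect_equal(m3$sleep_p50, unname(quantile(mv3$values[61:360], 0.5)))
  # WASO counts movement-rule violations even without recorded awakenings
  mv4 <- ms(rep(0, n)); mv4$values[200:230] <- 1
  expect_gt(sleep_metrics(rec, mv4)$waso_minutes, 0)
  expect_error(sleep_metrics(data.frame(onset = t0(), offset = t0() + 3000), mv),
               "shorter")
})

test_that("diary evaluation errors, summaries and sign convention", {
  sr <- data.frame(
    night_id = as.Date("2024-01-01") + 0:2,
    onset = t0("23:00:00") + (0:2) * 86400,
    offset = t0("07:00:00", "2024-01-02") + (0:2) * 86400,
    n_awakenings = 0L, is_main = TRUE)
  sr$awakenings <- replicate(3, interval_set(), simplify = FALSE)
  diary <- data.frame(night_id = sr$night_id, onset = sr$onset, offset = sr$offset)
  ev <- evaluate_against_diary(sr, diary)
  expect_equal(ev$summary$median, c(0, 0))
  expect_equal(ev$summary$iqr, c(0, 0))
  # constructed onset errors {-10, -20, -30} -> median -20
  diary2 <- diary; diary2$onset <- diary$onset + c(10, 20, 30) * 60
  ev2 <- evaluate_against_diary(sr, diary2)
  expect_equal(sort(ev2$per_night$onset_error), c(-30, -20, -10))
  expect_equal(ev2$summary$median[1], -20)
  # delaying detected onsets by +30 min shifts all onset errors by +30
  sr3 <- sr; sr3$onset <- sr$onset + 30 * 60
  ev3 <- evaluate_against_diary(sr3, diary2)
  expect_equal(ev3$per_night$onset_error, ev2$per_night$onset_error + 30)
  # unmatched nights are reported but excluded from the summary
  diary4 <- rbind(diary, data.frame(night_id = as.Date("2024-01-10"),
                                    onset = t0() + 9 * 86400, offset = t0() + 9.3 * 86400))
  ev4 <- evaluate_against_diary(sr, diary4)
  expect_equal(sum(ev4$per_night$matched), 3)
  expect_equal(ev4$summary$n[1], 3)
  # Bland-Altman pairs against a second method
  other <- data.frame(night_id = sr$night_id, onset = sr$onset + 600,
                      offset = sr$offset - 300)
  ev5 <- evaluate_against_diary(sr, diary, other = other)
  expect_equal(nrow(ev5$bland_altman), 6)
  expect_equal(unique(ev5$bland_altman$difference[ev5$bland_altman$measure == "onset"]),
               -10)
})

test_that("detector recovers the generator's sleep schedule end to end", {
  sim <- shared_sim()
  b <- shared_bundle()
  diary <- write_diary(sim$truth, 0)
  ev <- evaluate_against_diary(b$sleep_records, diary)
  expect_equal(sum(ev$per_night$matched), nrow(sim$truth$sleep))
  expect_lte(median(abs(ev$per_night$onset_error)), 15)
  expect_lte(median(abs(ev$per_night$offset_error)), 15)
})
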