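test_that("average_waveform matches direct column statistics", {
  m <- fold_days(activity_record(rep(rep(c(0L, 4L), each = 240), 10)))
  wf <- average_waveform(m)
  expect_equal(wf$mean, rep(c(0, 4), each = 240))
  expect_true(all(wf$sem == 0))

  two <- fold_days(activity_record(c(rep(0L, 480), rep(2L, 480))))
  wf2 <- average_waveform(two)
  expect_equal(wf2$mean, rep(1, 480))
  expect_equal(wf2$sem, rep(1, 480))

  set.seed(31)
  rec <- activity_record(rpois(480 * 6, 5))
  dm <- fold_days(rec)
  wf3 <- average_waveform(dm)
  raw <- matrix(rec$counts, nrow = 6, byrow = TRUE)
  expect_equal(wf3$mean, colMeans(raw))
  expect_equal(wf3$sem, apply(raw, 2, sd) / sqrt(6))

  one <- average_waveform(fold_days(activity_record(rpois(480, 5))))
  expect_true(all(is.na(one$sem)))
})

test_that("nocturnality: boundary cases and the complement identity", {
  all_dark <- square_record(on_min = 720, alpha_min = 700)
  expect_equal(as.numeric(nocturnality(all_dark)), 100)

  uniform <- activity_record(rep(3L, 4800))
  expect_equal(as.numeric(nocturnality(uniform)), 50)

  # nocturnality + diurnality = 100 for any record with positive days
  set.seed(7)
  rec <- activity_record(rpois(4800, 3))
  noct <- as.numeric(nocturnality(rec))
  sched <- rec$schedule
  rec_flip <- rec
  rec_flip$schedule <- light_schedule("LD", lights_on = list(c(12, 24)))
  diur <- as.numeric(nocturnality(rec_flip))  # dark window flipped to ZT 0-12
  expect_equal(noct + diur, 100)

  expect_error(nocturnality(activity_record(rep(0L, 960))), "positive total")
})

test_that("activity_rate is counts per recorded hour", {
  rec <- activity_record(rep(1L, 24), bin_minutes = 60)
  expect_equal(activity_rate(rec), 1)
  rec2 <- rec; rec2$counts <- rec$counts * 2L
  expect_equal(activity_rate(rec2), 2)

  set.seed(13)
  r <- activity_record(rpois(1000, 8), bin_minutes = 3)
  r$counts[c(5, 600)] <- NA
  expect_equal(activity_rate(r),
               sum(r$counts, na.rm = TRUE) / (998 * 3 / 60))
  expect_error(activity_rate(activity_record(rep(NA_integer_, 10))),
               "no recorded bins")
})

test_that("alpha is the longest circular suprathreshold span", {
  wf12 <- average_waveform(fold_days(square_record(alpha_min = 720)))
  expect_equal(as.numeric(alpha_duration(wf12)), 720)

  # sinusoid + constant: half the cycle sits above its mean (one-bin
  # slack for the grid points landing exactly on the mean)
  tt <- seq(0, 2 * pi, length.out = 481)[-481]
  sine <- structure(list(mean = 10 + sin(tt), sem = rep(0, 480),
                         bin_minutes = 3), class = "daily_waveform")
  expect_lte(abs(as.numeric(alpha_duration(sine)) - 720), 3)

  flat <- structure(list(mean = rep(2, 480), sem = rep(0, 480),
                         bin_minutes = 3), class = "daily_waveform")
  a <- alpha_duration(flat)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "arrhythmic"))

  # active phase wrapping midnight is measured circularly
  wrap <- average_waveform(fold_days(square_record(on_min = 1200,
                                                   alpha_min = 600)))
  expect_equal(as.numeric(alpha_duration(wrap)), 600)

  # invariance under additive constants and positive scaling
  set.seed(41)
  v <- rpois(480, 4) + sin(seq(0, 2 * pi, length.out = 480)) * 3
  mk <- function(x) structure(list(mean = x, sem = rep(0, 480),
                                   bin_minutes = 3),
                              class = "daily_waveform")
  a0 <- as.numeric(alpha_duration(mk(v)))
  expect_equal(as.numeric(alpha_duration(mk(v + 17))), a0)
  expect_equal(as.numeric(alpha_duration(mk(v * 3.5))), a0)
})

test_that("onsets are detected under the quiet/active rule", {
  rec <- square_record(n_days = 10, on_min = 720, alpha_min = 600)
  expect_equal(detect_onsets(fold_days(rec)), rep(720, 10))

  # one isolated suprathreshold bin in the quiet window is tolerated
  noisy <- rec
  noisy$counts[6 * 480 + 120] <- 60L   # day 7, ZT 6
  expect_equal(detect_onsets(fold_days(noisy)), rep(720, 10))

  # two violations disqualify the quiet window until later
  noisy2 <- rec
  noisy2$counts[6 * 480 + c(230, 236)] <- 60L  # ZT ~11.5 and ~11.8
  ons <- detect_onsets(fold_days(noisy2))
  expect_equal(ons[-7], rep(720, 9))

  set.seed(53)
  junk <- activity_record(rpois(4800, 5))
  expect_gt(sum(is.na(detect_onsets(fold_days(junk)))), 5)
})

test_that("onset precision is the mean absolute regression residual", {
  drift <- 720 - 22.8 * (0:9)   # tau 23.62 h free run
  expect_equal(onset_precision(drift), 0)

  # alternating +/-10 residuals orthogonal to the fitted line
  alt <- 500 + 10 * rep(c(1, -1, -1, 1), 2)
  expect_equal(onset_precision(alt), 10)

  set.seed(61)
  ons <- 700 - 15 * (0:9) + rnorm(10, 0, 20)
  fit <- lm(ons ~ I(1:10))
  expect_equal(onset_precision(ons), mean(abs(resid(fit))))

  expect_error(onset_precision(c(700, NA, 710, rep(NA, 5))),
               "insufficient onsets")

  # unwrapping: onsets crossing the 24-h boundary stay collinear
  wrapped <- (1400 + 30 * (0:9)) %% 1440
  expect_equal(onset_precision(wrapped), 0)
})

test_that("bout detection: merging, discarding, and the oracle", {
  mk <- function(active_min) {       # active_min: list of (start, len) min
    x <- integer(480)
    for (a in active_min) {
      i0 <- a[1] / 3 + 1
      x[i0:(i0 + a[2] / 3 - 1)] <- 50L
    }
    activity_record(x)
  }
  two <- activity_bouts(mk(list(c(60, 60), c(150, 60))))   # 30-min gap
  expect_equal(nrow(two), 2)
  one <- activity_bouts(mk(list(c(60, 60), c(138, 60))))   # 18-min gap
  expect_equal(nrow(one), 1)
  expect_equal(one$duration_minutes, 138)
  none <- activity_bouts(mk(list(c(60, 15))))
  expect_equal(nrow(none), 0)

  set.seed(71)
  for (i in 1:50) {
    counts <- rbinom(480, 1, 0.4) * rpois(480, 6)
    rec <- activity_record(counts)
    got <- activity_bouts(rec)
    want <- oracle_bouts(counts, 3)
    expect_equal(got$start_minute, (want$start - 1) * 3)
    expect_equal(got$end_minute, want$end * 3)
  }
})

test_that("circadian_metrics assembles the per-animal row", {
  p <- activity_sim_params(tau_hours = 23.62, nocturnality_target = 0.975)
  rec <- simulate_activity(p, light_schedule("LD"), n_days = 10)
  row <- circadian_metrics(rec)
  expect_equal(row$nocturnality_pct, 97.5, tolerance = 1e-3)
  expect_equal(row$tau_hours, 24)          # entrained under LD
  expect_equal(row$alpha_minutes, 612)     # 613 min quantized to 3-min bins
  expect_equal(row$precision_minutes, 0)
  expect_gt(row$power_pct, 50)
})
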