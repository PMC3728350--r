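test_that("the 40-s episode minimum is a hard boundary", {
  tr39 <- mobility_trace(c(rep(1, 39), rep(0, 61)))
  expect_equal(sum(score_sleep(tr39)$asleep), 0)
  tr40 <- mobility_trace(c(rep(1, 40), rep(0, 60)))
  expect_equal(sum(score_sleep(tr40)$asleep), 40)
})

test_that("scoring matches the brute-force run-length oracle", {
  set.seed(81)
  for (i in 1:100) {
    imm <- ifelse(rbinom(600, 1, 0.5) == 1,
                  runif(600, 0.9, 1), runif(600, 0, 0.9))
    tr <- mobility_trace(imm)
    expect_identical(score_sleep(tr)$asleep, oracle_sleep_flags(imm))
  }
})

test_that("per-minute aggregation is ZT-aligned and bounded", {
  imm <- c(rep(1, 90), rep(0, 30), rep(1, 60))   # 3 minutes
  ser <- score_sleep(mobility_trace(imm))
  expect_equal(ser$sleep_seconds, c(60, 30, 60))
  expect_true(all(ser$sleep_seconds >= 0 & ser$sleep_seconds <= 60))
  # partial leading minute dropped: start 30 s into a minute
  ser2 <- score_sleep(mobility_trace(imm[1:150], start_time = 30 / 3600))
  expect_equal(length(ser2$sleep_seconds), 2)
})

test_that("day/night totals: boundary placement and conservation", {
  # asleep exactly over ZT 0-12, awake 12-24
  imm <- rep(rep(c(1, 0), c(43200, 43200)), 2)
  tot <- sleep_totals(score_sleep(mobility_trace(imm)))
  expect_equal(tot$day_sleep_min, 720)
  expect_equal(tot$night_sleep_min, 0)

  none <- sleep_totals(score_sleep(mobility_trace(rep(0, 86400))))
  expect_equal(none$day_sleep_min + none$night_sleep_min, 0)

  set.seed(91)
  p <- sleep_sim_params(seed = 91)
  tr <- simulate_mobility(p, n_days = 2)
  ser <- score_sleep(tr)
  tot2 <- sleep_totals(ser)
  for (d in seq_len(nrow(tot2$per_day))) {
    day_min <- (d - 1) * 1440
    sel <- day_min + seq_len(1440)
    expect_equal(tot2$per_day$day_sleep_min[d] + tot2$per_day$night_sleep_min[d],
                 sum(ser$sleep_seconds[sel]) / 60)
  }
})

test_that("minute-level sleep bouts: thresholds, gaps, boundary splitting", {
  mk_series <- function(sleep_sec_per_min) {
    # a full day of per-minute sleep seconds, wrapped as a sleep_series
    structure(list(asleep = NULL, sleep_seconds = sleep_sec_per_min,
                   minute_zt_start = 0, schedule = light_schedule("LD"),
                   threshold = 0.95, min_seconds = 40, sample_seconds = 1),
              class = "sleep_series")
  }
  day <- rep(0, 1440)
  day[100:102] <- 45
  b <- sleep_bouts(mk_series(day))
  expect_equal(nrow(b$bouts), 1)
  expect_equal(b$bouts$duration_min, 3)

  day2 <- rep(0, 1440)
  day2[200:202] <- c(45, 30, 45)   # sub-threshold middle minute
  b2 <- sleep_bouts(mk_series(day2))
  expect_equal(nrow(b2$bouts), 2)
  expect_equal(b2$bouts$duration_min, c(1, 1))

  # a bout spanning ZT 12 is split so day/night accounting stays exact
  day3 <- rep(0, 1440)
  day3[715:726] <- 60
  b3 <- sleep_bouts(mk_series(day3))
  expect_equal(nrow(b3$bouts), 2)
  expect_equal(b3$bouts$window, c("day", "night"))
  expect_equal(sum(b3$bouts$duration_min), 12)

  set.seed(101)
  ssec <- sample(c(0, 20, 45, 60), 1440, replace = TRUE)
  got <- sleep_bouts(mk_series(ssec))
  # oracle: run lengths of >= 40-s minutes, split at the half-day boundary
  flag <- ssec >= 40
  halves <- list(1:720, 721:1440)
  want <- unlist(lapply(halves, function(ix) {
    r <- rle(flag[ix]); r$lengths[r$values]
  }))
  expect_equal(sort(got$bouts$duration_min), sort(want))
})

test_that("bout-duration distributions normalize to the daytime total", {
  p <- sleep_sim_params(mean_bout_min_day = 10, seed = 7)
  tr <- simulate_mobility(p, n_days = 2)
  b <- sleep_bouts(score_sleep(tr))
  dist <- bout_duration_distribution(b)
  expect_equal(sum(dist$fraction), 1)
  # hand-binned oracle
  dur <- b$bouts$duration_min[b$bouts$window == "day"]
  expect_equal(dist$fraction[1], mean(dur <= 30))

  fine <- bout_duration_distribution(b, fine = TRUE, fine_interval = 5)
  expect_equal(sum(fine$fraction), mean(dur < 30))
  expect_equal(fine$upper - fine$lower, rep(5, 6))
})

test_that("threshold sensitivity: identity, threshold logic, monotonicity", {
  always <- mobility_trace(rep(1, 2 * 86400))
  ts <- threshold_sensitivity(always)
  expect_equal(ts$metrics$day_sleep_min, rep(720, 3))
  expect_true(all(abs(as.matrix(ts$delta_pct[, -1])) < 1e-12))

  # immobility 0.93 only clears the 90% threshold
  imm <- rep(rep(c(0.93, 0.2), c(600, 600)), 144)
  ts2 <- threshold_sensitivity(mobility_trace(imm))
  m <- ts2$metrics
  expect_gt(m$day_sleep_min[m$threshold == 0.90], 0)
  expect_equal(m$day_sleep_min[m$threshold == 0.95], 0)
  expect_equal(m$day_sleep_min[m$threshold == 0.97], 0)

  # graded immobility: sleep non-increasing in threshold
  set.seed(111)
  p <- sleep_sim_params(immobility_in_sleep = 0.96, jitter_sd = 0.03,
                        seed = 111)
  tr <- simulate_mobility(p, n_days = 2)
  ts3 <- threshold_sensitivity(tr)
  m3 <- ts3$metrics[order(ts3$metrics$threshold), ]
  tot <- m3$day_sleep_min + m3$night_sleep_min
  expect_true(all(diff(tot) <= 0))
})

test_that("total sleep is non-increasing in the episode minimum", {
  set.seed(121)
  p <- sleep_sim_params(seed = 121)
  tr <- simulate_mobility(p, n_days = 1)
  mins <- c(20, 40, 80, 160)
  tots <- vapply(mins, function(ms)
    sum(score_sleep(tr, min_seconds = ms)$asleep), 0)
  expect_true(all(diff(tots) <= 0))
})

test_that("bout minutes obey the bin-quantization bound against sleep time", {
  # scored series: each bout minute holds >= 40 s, and only episode-edge
  # minutes can be partial, so bout minutes <= sleep minutes + bout count
  set.seed(131)
  for (s in 1:5) {
    p <- sleep_sim_params(seed = s)
    tr <- simulate_mobility(p, n_days = 1)
    ser <- score_sleep(tr)
    b <- sleep_bouts(ser)
    tot <- sleep_totals(ser)
    nb <- nrow(b$bouts)
    expect_lte(sum(b$bouts$duration_min),
               tot$day_sleep_min + tot$night_sleep_min + nb)
  }
})
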