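test_that("simulations are reproducible and deterministic when noiseless", {
  p <- activity_sim_params(tau_hours = 23.8, onset_jitter_sd_min = 10,
                           noise = "POISSON", seed = 42)
  r1 <- simulate_activity(p, light_schedule("DD"), n_days = 6)
  r2 <- simulate_activity(p, light_schedule("DD"), n_days = 6)
  expect_identical(r1$counts, r2$counts)

  q <- activity_sim_params(tau_hours = 24)
  det <- simulate_activity(q, light_schedule("DD"), n_days = 5)
  m <- fold_days(det)
  for (d in 2:5) expect_equal(m[d, ], m[1, ])  # identical days

  s <- sleep_sim_params(seed = 9)
  t1 <- simulate_mobility(s, n_days = 1)
  t2 <- simulate_mobility(s, n_days = 1)
  expect_identical(t1$immobility, t2$immobility)
})

test_that("generated onsets drift at (tau - 24) * 60 min per day", {
  p <- activity_sim_params(tau_hours = 23.62)
  rec <- simulate_activity(p, light_schedule("DD"), n_days = 10)
  ons <- attr(rec, "onsets_true")
  expect_equal(diff(ons), rep(-22.8, 9))
})

test_that("parameter values are recovered across a tau x jitter grid", {
  for (tau in c(23.6, 23.8, 24.0)) {
    for (jit in c(0, 10, 20)) {
      p <- activity_sim_params(tau_hours = tau, onset_jitter_sd_min = jit,
                               seed = 1000 + round(100 * tau) + jit)
      rec <- simulate_activity(p, light_schedule("DD"), n_days = 10)
      est <- chisq_periodogram(rec)$tau_hours
      expect_lte(abs(est - tau), 0.05 + jit / 60 * 0.05)

      ons <- detect_onsets(fold_days(rec))
      prec <- onset_precision(ons)
      # analytic target: mean |residual| of the injected jitter itself
      true_ons <- attr(rec, "onsets_true")
      fit <- lm(true_ons ~ I(seq_along(true_ons)))
      expect_lte(abs(prec - mean(abs(resid(fit)))), 2)
    }
  }
})

test_that("nocturnality reallocation hits its target", {
  p <- activity_sim_params(tau_hours = 24, nocturnality_target = 0.85)
  rec <- simulate_activity(p, light_schedule("LD"), n_days = 10)
  expect_equal(as.numeric(nocturnality(rec)), 85, tolerance = 1e-3)
})

test_that("pulse experiments place the shift where the analysis expects it", {
  p <- activity_sim_params(tau_hours = 23.62)
  rec <- simulate_pulse_experiment(p, n_days = 16, pulse_day = 8,
                                   imposed_delay_min = 113)
  ons <- attr(rec, "onsets_true")
  expect_equal(ons[9] - ons[8], -23 + 113)  # abrupt shift after the pulse
  expect_equal(attr(rec, "imposed_delay_min"), 113)

  ramp <- simulate_pulse_experiment(p, n_days = 16, pulse_day = 8,
                                    imposed_delay_min = 90,
                                    transient_days = 2)
  o <- attr(ramp, "onsets_true") - (720 - 23 * (0:15))
  expect_equal(o[9:12], c(30, 60, 90, 90))

  expect_error(simulate_pulse_experiment(p, n_days = 10, pulse_day = 10,
                                         imposed_delay_min = 60),
               "inside the record")
})

test_that("mobility generator: boundary fractions and truth agreement", {
  allday <- sleep_sim_params(day_sleep_fraction = 1,
                             night_sleep_fraction = 0,
                             immobility_in_sleep = 1, seed = 3)
  tr <- simulate_mobility(allday, n_days = 2)
  tot <- sleep_totals(score_sleep(tr))
  expect_equal(tot$day_sleep_min, 720)
  expect_equal(tot$night_sleep_min, 0)

  p <- sleep_sim_params(seed = 17)
  tr2 <- simulate_mobility(p, n_days = 1)
  truth <- attr(tr2, "truth")
  flags <- logical(length(tr2$immobility))
  for (r in seq_len(nrow(truth)))
    flags[(truth$start_sec[r] + 1):truth$end_sec[r]] <- TRUE
  expect_identical(score_sleep(tr2)$asleep, flags)

  expect_error(sleep_sim_params(mean_bout_min_day = 0.5), "infeasible")
})
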