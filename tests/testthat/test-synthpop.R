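test_that("attention states are constant in focused conditions and switch in AB", {
  set.seed(10)
  p <- attention_model_params()
  ai <- sample_attention_state("AI", 500, p)
  expect_true(all(ai$state == "rf"))
  expect_equal(length(unique(ai$a)), 1L)
  ao <- sample_attention_state("AO", 500, p)
  expect_true(all(ao$state == "away"))
  # degenerate limit: no within-trial switching
  p0 <- attention_model_params(within_trial_switch_hz = 0)
  ab0 <- replicate(50, length(unique(sample_attention_state("AB", 300, p0)$state)))
  expect_true(all(ab0 == 1))
  # mean dwell ~ 250 ms at 4 Hz
  p4 <- attention_model_params(within_trial_switch_hz = 4)
  dwells <- unlist(lapply(1:200, function(i) {
    st <- sample_attention_state("AB", 4000, p4)$state
    r <- rle(st)$lengths
    if (length(r) > 2) r[2:(length(r) - 1)] * 10 else numeric(0)  # interior dwells, ms
  }))
  expect_equal(mean(dwells), 250, tolerance = 0.05 * 250)
})

test_that("AB reduces to AI/AO when switching is off and the prior is degenerate", {
  p <- attention_model_params(within_trial_switch_hz = 0, focused_state_sd = 0.1,
                              ab_state_separation = 1.03 - 0.98,
                              p_attend_both = 0, ab_state_prior = 1)
  set.seed(77); ab <- sample_attention_state("AB", 100, p)
  set.seed(77); ai <- sample_attention_state("AI", 100, p)
  # same RNG stream consumption is not guaranteed, so compare distributions
  # through the deterministic part: with matched jitter the gains coincide
  expect_equal(unique(ab$a) - ab$jitter, unique(ai$a) - ai$jitter,
               tolerance = 1e-12)
  p0 <- attention_model_params(within_trial_switch_hz = 0, focused_state_sd = 0,
                               ab_state_separation = 1.03 - 0.98,
                               p_attend_both = 0, ab_state_prior = 0)
  ab0 <- sample_attention_state("AB", 100, p0)
  ao0 <- sample_attention_state("AO", 100, p0)
  expect_equal(ab0$a, ao0$a)
})

test_that("spike simulator is Poisson in the homogeneous limit", {
  set.seed(11)
  stim <- stimulus_params()
  units <- make_unit_roster(1, 1)
  units$amplitude <- 0; units$baseline <- 30
  units$common_noise_loading <- 0; units$offset_coupling <- 0
  counts <- replicate(600, {
    sp <- simulate_spike_trains(sample(0:35, 100, TRUE), units,
                                a = rep(0, 100), params = stim)
    nrow(sp)
  })
  expect_equal(mean(counts), 30, tolerance = 0.05 * 30)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.15)
})

test_that("simulated rates track the planted tuning and attention gain", {
  set.seed(12)
  stim <- stimulus_params()
  units <- make_unit_roster(1, 2)
  units$pref_deg <- 0; units$kappa <- 1.5; units$baseline <- 5
  units$amplitude <- 40; units$gain_coupling <- 1; units$offset_coupling <- 0
  units$common_noise_loading <- 0
  codes <- rep(0L, 300)  # constant preferred orientation
  n_att <- sum(replicate(200, nrow(
    simulate_spike_trains(codes, units, a = rep(0.2, 300), params = stim))))
  n_neu <- sum(replicate(200, nrow(
    simulate_spike_trains(codes, units, a = rep(0, 300), params = stim))))
  # rate = baseline + (1 + a) * amplitude at preferred orientation
  expect_equal(n_att / n_neu, (5 + 1.2 * 40) / (5 + 40), tolerance = 0.04)
})

test_that("behavioral generator saturates, respects the lockout, and obeys hazards", {
  stim <- stimulus_params()
  trial <- list(zcp_s = 1.5, coherence = 30, change_side = "left",
                is_catch = FALSE)
  set.seed(13)
  bp <- behavior_params(fa_hazard_hz = 0)
  res <- replicate(300, simulate_behavior(trial, "rf", bp, "left", stim)$saccade_side)
  expect_gt(mean(res == "left"), 0.995)  # detection probability ~ 1
  rts <- replicate(300, simulate_behavior(trial, "rf", bp, "left", stim)$saccade_ms)
  expect_true(all(rts - 1500 >= bp$lockout_ms))
  expect_true(all(rts - 1500 <= 300 + 200))
  # no hazard, no change -> fixation maintained on every catch trial
  catch <- list(zcp_s = 1.5, coherence = 0, change_side = "none", is_catch = TRUE)
  out <- replicate(100, simulate_behavior(catch, "rf", bp, "left", stim)$saccade_side)
  expect_true(all(out == "none"))
})

test_that("planted eye-movement events exceed the velocity criterion by design", {
  set.seed(14)
  tr <- simulate_eye_trace(30000, eye_params(), n_events = 40)
  expect_equal(nrow(tr$events), 40)
  # every planted event moves faster than 0.15 deg per 10 ms on average
  expect_true(all(tr$events$amplitude_deg / tr$events$duration_ms * 10 >= 0.15 - 1e-9))
  quiet <- simulate_eye_trace(5000, eye_params(), n_events = 0)
  expect_equal(nrow(detect_microsaccades(quiet$t_ms, quiet$x, quiet$y)), 0L)
})

test_that("synthetic LFP carries its sink where planted", {
  lfp <- simulate_lfp(32, 20, noise_sd = 0)
  csd <- compute_csd(lfp)
  expect_equal(csd$earliest_sink_channel, 20L)
  # a potential linear in depth has zero CSD on interior channels
  lin <- outer(seq_len(32), rep(1, 50))
  c2 <- compute_csd(lin, smooth_sd_ch = 0)
  expect_equal(max(abs(c2$csd[2:31, ])), 0)
})
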