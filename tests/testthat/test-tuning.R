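test_that("tuning regression recovers a planted 50 ms latency and preference", {
  set.seed(30)
  d <- make_tuned_unit_data(n_trials = 50, pref_deg = 60, latency_ms = 50)
  tc <- estimate_tuning(d$spikes, d$codes)
  expect_equal(tc$optimal_latency_ms, 50)
  pref_hat <- tc$grid[which.max(tc$curve)]
  expect_lte(min(abs(pref_hat - 60), 180 - abs(pref_hat - 60)), 10)
  # latency-scan consistency: joint-fit weights at the optimal lag rank
  # orientations like the single-lag refit
  expect_gt(cor(rank(tc$joint_weights[, 5]), rank(tc$curve)), 0.9)
})

test_that("noiseless one-hot responses are reproduced exactly at the planted lag", {
  set.seed(31)
  g <- c(rep(0, 30), 1, 2, 3, 2, 1, 0)  # generative tuning vector, lag 3
  codes <- lapply(1:8, function(i) sample(0:35, 120, replace = TRUE))
  spikes <- lapply(codes, function(cd) {
    y <- c(rep(0, 3), g[cd[1:(length(cd) - 3)] + 1])
    rep((seq_along(y) - 1) * 10 + 5, y)
  })
  tc <- estimate_tuning(spikes, codes)
  expect_equal(tc$optimal_latency_ms, 30)
  expect_equal(tc$curve, g, tolerance = 1e-6)
})

test_that("orientation-blind units have flat weights and a flat lag profile", {
  set.seed(32)
  d <- make_untuned_unit_data(n_trials = 60, n_frames = 200, rate_per_bin = 0.4)
  tc <- estimate_tuning(d$spikes, d$codes)
  expect_lt(sd(tc$curve) / mean(tc$curve), 0.15)
  expect_lt(max(tc$lag_variance) / max(mean(tc$lag_variance), 1e-12), 3)
})

test_that("the permutation test is extreme for tuned units and null for flat ones", {
  set.seed(33)
  d <- make_tuned_unit_data(n_trials = 40, amplitude = 60)
  tc <- estimate_tuning(d$spikes, d$codes)
  expect_equal(tuning_significance(tc, n_perm = 1000), 1 / 1001)
  expect_equal(attnvar:::tuning_statistic(rep(1, 36)), 0)  # equal weights project to zero
  expect_error(tuning_significance(tc, n_perm = 0), "n_perm")
})

test_that("visual responsiveness is a paired t-test with the closed-form value", {
  pre <- c(5, 6, 7); post <- c(9, 10, 12)
  dif <- post - pre
  t_hand <- mean(dif) / (sd(dif) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_hand), 2)
  expect_equal(visual_responsiveness(pre, post), p_hand)
  set.seed(34)
  expect_lt(visual_responsiveness(rpois(40, 5), rpois(40, 5) + 10), 1e-10)
  expect_error(visual_responsiveness(5, 9), "2 trials")
})

test_that("SDFs normalize to the Attend-Out plateau", {
  trials <- data.frame(trial = 1:30,
                       condition = rep(c("AI", "AB", "AO"), each = 10),
                       seed_id = rep(0:4, 6), outcome = "hit")
  set.seed(35)
  # constant-rate unit: 1 spike per 50 ms bin on average in AO/AB, doubled in AI
  mk <- function(rate_hz) sort(runif(rpois(1, rate_hz), 0, 1000))
  spikes <- lapply(1:30, function(i) mk(if (i <= 10) 40 else 20))
  m <- spike_density_function(spikes, trials)
  s <- session_sdf(list(m))
  plateau <- function(row) mean(s[row, 3:20])
  expect_equal(plateau("AO"), 1, tolerance = 0.15)
  expect_equal(plateau("AI") / plateau("AO"), 2, tolerance = 0.2)
  trials$outcome[trials$condition == "AB"] <- "miss"
  expect_warning(spike_density_function(spikes, trials), "excluded")
})

test_that("spike-triggered averaging recovers a planted receptive field", {
  set.seed(36)
  nx <- 8; ny <- 8; n_epochs <- 4000
  dots <- data.frame(t_on_ms = (seq_len(n_epochs) - 1) * 30,
                     x = sample(nx, n_epochs, TRUE),
                     y = sample(ny, n_epochs, TRUE),
                     color = sample(c(-1, 1), n_epochs, TRUE))
  drive <- dots$x == 5 & dots$y == 3 & dots$color == 1
  spikes <- dots$t_on_ms[drive] + 50 + runif(sum(drive), 0, 10)
  sta <- sta_receptive_field(spikes, dots, nx, ny, lag_ms = 50)
  expect_equal(unname(sta$peak), c(5, 3))
  # stimulus-blind unit: map near zero everywhere
  blind <- runif(500, 0, n_epochs * 30)
  sta0 <- sta_receptive_field(blind, dots, nx, ny)
  expect_lt(max(abs(sta0$map)), 0.2)
  expect_error(sta_receptive_field(numeric(0), dots, nx, ny), "no spikes")
})

test_that("signal correlation behaves for identical, orthogonal and flat curves", {
  w1 <- make_vm_curve(w4 = 0)
  w2 <- make_vm_curve(w4 = pi)  # preferred orientations 90 deg apart
  expect_equal(signal_correlation(w1 - mean(w1), w1 - mean(w1)), 1)
  expect_lt(signal_correlation(w1 - mean(w1), w2 - mean(w2)), 0)
  expect_warning(r <- signal_correlation(rep(0, 36), w1 - mean(w1)), "flat")
  expect_true(is.na(r))
})
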