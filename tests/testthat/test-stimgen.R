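test_that("ZCP durations respect bounds and the calibrated truncated mean", {
  params <- stimulus_params()
  set.seed(1)
  d <- sample_zcp_duration(50000, params)
  expect_true(all(d >= params$zcp_min_s & d <= params$zcp_max_s))
  expect_equal(mean(d), 2.17, tolerance = 0.02)
  # calibrated rate agrees with numerical integration of the truncated density
  l <- zcp_rate(params)
  a <- params$zcp_min_s; b <- params$zcp_max_s
  quad <- integrate(function(x) x * l * exp(-l * x) /
                      (exp(-l * a) - exp(-l * b)), a, b)$value
  expect_equal(quad, 2.17, tolerance = 1e-8)
  # the naive rate 1/2.17 would give a truncated mean near 1.62 s, so the
  # calibration is load-bearing
  l0 <- 1 / 2.17
  naive <- integrate(function(x) x * l0 * exp(-l0 * x) /
                       (exp(-l0 * a) - exp(-l0 * b)), a, b)$value
  expect_equal(naive, 1.624, tolerance = 0.001)
  expect_lt(l, l0)
})

test_that("ZCP sampler matches the truncated-exponential CDF (KS < 0.01)", {
  params <- stimulus_params()
  set.seed(2)
  d <- sample_zcp_duration(1e5, params)
  l <- zcp_rate(params)
  a <- params$zcp_min_s; b <- params$zcp_max_s
  cdf <- function(x) (exp(-l * a) - exp(-l * x)) / (exp(-l * a) - exp(-l * b))
  ks <- max(abs(ecdf(d)(sort(d)) - cdf(sort(d))))
  expect_lt(ks, 0.01)
})

test_that("orientation sequences obey the permutation-block constraints", {
  s <- generate_orientation_sequence(0, 10000, side = "left")
  expect_length(unique(s$frames), 36)
  expect_true(all(s$frames %in% seq(0, 175, by = 5)))
  one_block <- generate_orientation_sequence(1, 36, side = "left")
  expect_equal(sort(one_block$codes), 0:35)
  # any 30-frame window holds a given orientation at most twice
  long <- generate_orientation_sequence(2, 100000, side = "right")
  worst <- max(vapply(0:35, function(k) {
    runsum <- stats::filter(as.numeric(long$codes == k), rep(1, 30), sides = 1)
    max(runsum, na.rm = TRUE)
  }, numeric(1)))
  expect_lte(worst, 2)
})

test_that("sequences are reproducible, prefix-stable, and side-distinct", {
  a1 <- generate_orientation_sequence(3, 500, side = "left", session_seed = 5)
  a2 <- generate_orientation_sequence(3, 500, side = "left", session_seed = 5)
  expect_identical(a1$codes, a2$codes)
  short <- generate_orientation_sequence(3, 50, side = "left", session_seed = 5)
  expect_identical(a1$codes[1:50], short$codes)
  r <- generate_orientation_sequence(3, 500, side = "right", session_seed = 5)
  expect_false(identical(a1$codes, r$codes))
  expect_error(generate_orientation_sequence(7, 10, side = "left"),
               "unknown seed")
})

test_that("coherent-period embedding plants exactly the designed signal count", {
  set.seed(3)
  params <- stimulus_params()
  for (coh in c(0, 4, 17, 30)) {
    s <- generate_orientation_sequence(0, 150, params, "right")
    e <- embed_coherent_period(s, coh, cp_start_frame = 100)
    cp <- 101:130
    expect_equal(sum(e$signal_mask), coh)
    expect_equal(sum(e$frames[cp] == 45), coh)  # right signal is 45 deg
    expect_true(all(which(e$signal_mask) %in% cp))
  }
  s <- generate_orientation_sequence(0, 150, params, "left")
  e <- embed_coherent_period(s, 30, cp_start_frame = 100)
  expect_true(all(e$frames[101:130] == 135))  # left signal is 135 deg
  expect_error(embed_coherent_period(s, 31, 100), "out of range")
})

test_that("session schedules have the paradigm's block and trial structure", {
  set.seed(4)
  sch <- build_session_schedule(list(
    base_coherences = c(2, 4, 6, 8, 10), rf_side = "left",
    n_blocks = 60, trials_per_block = 100))
  expect_lt(abs(mean(sch$is_catch) - 0.10), 0.012)
  expect_true(all(sch$is_catch == (sch$change_side == "none")))
  # every consecutive triple of blocks shows all three conditions
  bc <- unique(sch[, c("block", "condition")])$condition
  for (i in seq(1, 58, by = 3))
    expect_setequal(bc[i:(i + 2)], c("AI", "AB", "AO"))
  ai <- sch[sch$condition == "AI" & !sch$is_catch, ]
  ao <- sch[sch$condition == "AO" & !sch$is_catch, ]
  ab <- sch[sch$condition == "AB" & !sch$is_catch, ]
  expect_true(all(ai$change_side == "left"))
  expect_true(all(ao$change_side == "right"))
  expect_equal(mean(ab$change_side == "left"), 0.5, tolerance = 0.03)
  expect_setequal(unique(ab$coherence), c(3, 5, 7, 9, 11))  # base + 1
  expect_error(build_session_schedule(list(
    base_coherences = c(2, 4), rf_side = "left", n_blocks = 3)),
    "at least 5")
})
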