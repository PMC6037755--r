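test_that("shift correction removes stimulus-locked correlation", {
  set.seed(60)
  # two independent Poisson trains sharing a strong rate modulation
  T <- 400; n <- 300
  rate <- 40 * (1 + 0.8 * sin(2 * pi * (seq_len(T) - 1) / 100)) / 1000  # per ms
  mkt <- function() lapply(seq_len(n), function(i) which(runif(T) < rate) - 0.5)
  spA <- mkt(); spB <- mkt()
  cg <- cross_correlogram(spA, spB, T_ms = T)
  # corrected CCG indistinguishable from zero: band test on the mean
  band <- abs(cg$lags) <= 100
  m <- mean(cg$ccg[band])
  se <- sd(cg$ccg[band]) / sqrt(sum(band))
  expect_lt(abs(m), 3 * se + 1e-12)
  # the predictor absorbs the stimulus-locked structure of the raw CCG
  # (large lags excluded: the lag-overlap normalization amplifies noise there)
  mid <- abs(cg$lags) <= 300
  expect_lt(sd(cg$ccg[mid]), 0.5 * sd(cg$raw[mid]))
})

test_that("a delayed copy peaks at its lag and symmetry is exact", {
  set.seed(61)
  spA <- lapply(1:30, function(i) sort(runif(rpois(1, 15), 0, 900)))
  spB <- lapply(spA, function(t) t + 5)
  cab <- cross_correlogram(spA, spB, T_ms = 1000)
  expect_equal(cab$lags[which.max(cab$corrected)], 5)
  cba <- cross_correlogram(spB, spA, T_ms = 1000)
  expect_equal(cab$corrected, rev(cba$corrected))
  expect_error(cross_correlogram(list(numeric(0)), list(numeric(0))),
               "no spikes")
})

test_that("r_CCG at the full window equals the spike-count correlation", {
  set.seed(62)
  p <- make_gain_pair(400, T_ms = 1000)
  cjk <- cross_correlogram(p$spA, p$spB, T_ms = 1000)
  cjj <- cross_correlogram(p$spA, p$spA, T_ms = 1000)
  ckk <- cross_correlogram(p$spB, p$spB, T_ms = 1000)
  rc <- cumulative_r_ccg(cjk, cjj, ckk)
  r_count <- cor(lengths(p$spA), lengths(p$spB))
  expect_equal(rc$r_ccg[1000], r_count, tolerance = 1e-10)
  expect_equal(nrow(rc), 1000)
  # an independent pair stays near zero at every lag window
  set.seed(63)
  q1 <- lapply(1:800, function(i) sort(runif(rpois(1, 20), 0, 1000)))
  q2 <- lapply(1:800, function(i) sort(runif(rpois(1, 20), 0, 1000)))
  rc0 <- cumulative_r_ccg(cross_correlogram(q1, q2, T_ms = 1000),
                          cross_correlogram(q1, q1, T_ms = 1000),
                          cross_correlogram(q2, q2, T_ms = 1000))
  expect_lt(max(abs(rc0$r_ccg)), 0.12)
  expect_lt(abs(rc0$r_ccg[1000]), 0.1)
})

test_that("seed-matched predictors handle stimuli that differ across seeds", {
  set.seed(64)
  # seed-specific rate profiles; independent units within seed
  T <- 300
  prof <- list(rep(0.02, T), 0.02 * (1 + cos(2 * pi * seq_len(T) / 150)))
  seed <- rep(c(0L, 1L), each = 40)
  mk <- function() lapply(seed, function(s) which(runif(T) < prof[[s + 1]]) - 0.5)
  spA <- mk(); spB <- mk()
  cg <- cross_correlogram(spA, spB, seed = seed, T_ms = T)
  band <- abs(cg$lags) <= 80
  expect_lt(abs(mean(cg$ccg[band])),
            3 * sd(cg$ccg[band]) / sqrt(sum(band)) + 1e-12)
})

test_that("session-level r_CCG curves agree with the per-pair computation", {
  set.seed(65)
  p <- make_gain_pair(60, T_ms = 500)
  spikes <- rbind(
    data.frame(unit = 1L, trial = rep(seq_along(p$spA), lengths(p$spA)),
               time_ms = unlist(p$spA)),
    data.frame(unit = 2L, trial = rep(seq_along(p$spB), lengths(p$spB)),
               time_ms = unlist(p$spB)))
  trials <- data.frame(trial = seq_along(p$spA), condition = "AI", seed_id = 0L)
  sr <- session_rccg(spikes, trials, units = c(1L, 2L), T_ms = 500,
                     tau_subset = c(100, 500))
  rc <- cumulative_r_ccg(cross_correlogram(p$spA, p$spB, T_ms = 500),
                         cross_correlogram(p$spA, p$spA, T_ms = 500),
                         cross_correlogram(p$spB, p$spB, T_ms = 500))
  expect_equal(sr$r_ccg[sr$tau_ms == 100], rc$r_ccg[100], tolerance = 1e-10)
  expect_equal(sr$r_ccg[sr$tau_ms == 500], rc$r_ccg[500], tolerance = 1e-10)
})
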