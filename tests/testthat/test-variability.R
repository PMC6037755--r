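test_that("block-wise z-scoring reduces to plain z-scoring with one block", {
  set.seed(50)
  counts <- make_count_table(rpois(20, 10))
  z <- blockwise_zscore(counts)
  expect_equal(z$z, as.numeric(scale(counts$count)))
  # constant cells are dropped
  const <- make_count_table(rep(4, 10))
  expect_error(blockwise_zscore(const), "degenerate")
  mix <- rbind(make_count_table(rep(4, 10), seed_id = 0L),
               make_count_table(rpois(10, 8), seed_id = 1L))
  mix$trial <- seq_len(nrow(mix))
  z2 <- blockwise_zscore(mix)
  expect_true(all(z2$seed_id == 1L))
})

test_that("small cells fall back to per-seed statistics", {
  set.seed(51)
  big <- make_count_table(rpois(12, 10), block = 1L)
  small <- make_count_table(rpois(2, 10), block = 2L)
  small$trial <- small$trial + 12
  z <- blockwise_zscore(rbind(big, small))
  expect_equal(nrow(z), 14)  # the 2-trial block survives via (unit, seed) pooling
  m <- mean(c(big$count, small$count)); s <- sd(c(big$count, small$count))
  expect_equal(z$z[z$trial == 13], (small$count[1] - m) / s)
})

test_that("block-wise z-scoring removes planted slow drift from r_sc", {
  set.seed(52)
  n_blocks <- 10; per_block <- 40
  drift <- exp(cumsum(rnorm(n_blocks, 0, 0.35)))
  rho_gain_sd <- 0.12
  rows <- list()
  for (b in seq_len(n_blocks)) {
    g <- exp(rnorm(per_block, 0, rho_gain_sd))  # shared gain, the true correlation source
    for (u in 1:2) {
      mu <- 20 * drift[b] * g
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, trial = (b - 1) * per_block + seq_len(per_block),
        condition = "AI", seed_id = 0L, block = b, count = rpois(per_block, mu))
    }
  }
  counts <- do.call(rbind, rows)
  z <- blockwise_zscore(counts)
  r_block <- pairwise_rsc(z)$r_sc
  naive <- counts
  naive$block <- 1L
  r_naive <- pairwise_rsc(blockwise_zscore(naive))$r_sc
  # oracle: moment formula for the doubly stochastic (shared log-normal gain)
  # model, cov = mu^2 * (e^{s^2} - 1), var = mu + mu^2 (e^{s^2} - 1)
  mu <- 20; v <- exp(rho_gain_sd^2) - 1
  r_true <- mu^2 * v / (mu + mu^2 * v)
  expect_lt(abs(r_block - r_true), 0.08)
  expect_gt(r_naive, r_block + 0.1)  # drift inflates the naive estimate
})

test_that("spike-count correlation handles identity, independence and few trials", {
  set.seed(53)
  z <- rnorm(50)
  expect_equal(spike_count_correlation(z, z), 1)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(spike_count_correlation(a, b)), 0.03)
  expect_warning(r <- spike_count_correlation(c(1, 2), c(3, 4)), "undefined")
  expect_true(is.na(r))
})

test_that("Fano factors match hand arithmetic and the Poisson limit", {
  expect_equal(fano_factor(make_count_table(c(1, 1, 1)))$fano, 0)
  # counts [0, 2]: unbiased var 2, mean 1 -> F = 2 (needs min_trials = 2)
  expect_equal(fano_factor(make_count_table(c(0, 2)), min_trials = 2)$fano, 2)
  set.seed(54)
  f <- fano_factor(make_count_table(rpois(4000, 9)))$fano
  expect_equal(f, 1, tolerance = 0.06)
})

test_that("eccentricity trend reproduces the published t-statistic form", {
  expect_equal(eccentricity_trend(1:10, (1:10) * 2 + 3)$r, 1)
  # r = 0.44 at n = 52 gives t close to the reported 3.5
  set.seed(55)
  n <- 52
  x <- rnorm(n); e <- rnorm(n)
  e <- residuals(lm(e ~ x))  # orthogonalize, then mix to exact r
  r_target <- 0.44
  y <- r_target * scale(x)[, 1] + sqrt(1 - r_target^2) * scale(e)[, 1]
  tr <- eccentricity_trend(y, x)
  expect_equal(tr$r, 0.44, tolerance = 1e-10)
  expect_equal(tr$t, 3.5, tolerance = 0.05)
  expect_lt(tr$p, 0.01)
  # permutation null is centered on zero
  perm <- replicate(200, eccentricity_trend(sample(y), x)$r)
  expect_lt(abs(mean(perm)), 0.05)
  expect_error(eccentricity_trend(1:5, rep(2, 5)), "constant")
})

test_that("r_sc is invariant to per-unit affine transforms within cells", {
  set.seed(56)
  counts <- rbind(make_count_table(rpois(15, 10), unit = 1L),
                  make_count_table(rpois(15, 12), unit = 2L))
  counts$trial <- rep(1:15, 2)
  r1 <- pairwise_rsc(blockwise_zscore(counts))$r_sc
  counts2 <- counts
  counts2$count[counts2$unit == 2L] <- counts2$count[counts2$unit == 2L] * 3 + 7
  r2 <- pairwise_rsc(blockwise_zscore(counts2))$r_sc
  expect_equal(r1, r2)
})
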