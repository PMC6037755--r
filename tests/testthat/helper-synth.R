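# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no stored data.

# Pair of stationary, gain-coupled Poisson spike trains: a doubly stochastic
# model with a shared log-normal gain per trial.
make_gain_pair <- function(n_trials, T_ms = 1000, mu_a = 20, mu_b = 25,
                           gain_sd = 0.15) {
  g <- exp(rnorm(n_trials, -gain_sd^2 / 2, gain_sd))
  spA <- lapply(seq_len(n_trials), function(i)
    sort(runif(rpois(1, mu_a * g[i]), 0, T_ms)))
  spB <- lapply(seq_len(n_trials), function(i)
    sort(runif(rpois(1, mu_b * g[i]), 0, T_ms)))
  list(spA = spA, spB = spB, gain = g)
}

# Spike-time lists plus matching orientation-code lists for a single
# synthetic tuned unit driven by the permutation-stream stimulus.
make_tuned_unit_data <- function(n_trials = 40, n_frames = 200,
                                 pref_deg = 60, kappa = 1.5, baseline = 8,
                                 amplitude = 40, latency_ms = 50,
                                 session_seed = 11) {
  stim <- stimulus_params()
  units <- make_unit_roster(1, session_seed)
  units$pref_deg <- pref_deg; units$kappa <- kappa
  units$baseline <- baseline; units$amplitude <- amplitude
  units$latency_ms <- latency_ms
  units$common_noise_loading <- 0
  codes <- lapply(seq_len(n_trials), function(i)
    generate_orientation_sequence((i - 1) %% 5, n_frames, stim, "left",
                                  session_seed + i)$codes)
  sp <- lapply(codes, function(cd)
    simulate_spike_trains(cd, units, a = rep(0, length(cd)), drift = 1,
                          z = NULL, params = stim)$time_ms)
  list(spikes = sp, codes = codes, stim = stim)
}

# Untuned (orientation-blind) Poisson unit over the same stimulus format.
make_untuned_unit_data <- function(n_trials = 10, n_frames = 151,
                                   rate_per_bin = 0.25) {
  codes <- lapply(seq_len(n_trials), function(i)
    sample(0:35, n_frames, replace = TRUE))
  sp <- lapply(codes, function(cd) {
    k <- rpois(length(cd), rate_per_bin)
    rep((seq_along(cd) - 1) * 10, k) + runif(sum(k), 0, 10)
  })
  list(spikes = sp, codes = codes)
}

# Noisy von Mises tuning curve from known parameters.
make_vm_curve <- function(w1 = 2, w2 = 1, w3 = 1.5, w4 = pi / 2,
                          noise_sd = 0) {
  x <- 2 * (0:35) * 5 * pi / 180
  w1 + exp(w2 + w3 * cos(x - w4)) + rnorm(36, 0, noise_sd)
}

# Count table in the block-wise z-scoring layout.
make_count_table <- function(counts_by_trial, condition = "AI",
                             seed_id = 0L, block = 1L, unit = 1L) {
  data.frame(unit = unit, trial = seq_along(counts_by_trial),
             condition = condition, seed_id = seed_id, block = block,
             count = counts_by_trial)
}
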