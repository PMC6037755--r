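#' Parameters of the latent attention-state model
#'
#' The generative model treats attention as a population-wide latent variable
#' `a(t)` (0 = neutral) that multiplies tuned drive and/or adds to baseline
#' according to each unit's coupling. Two aspects are parameterized
#' separately, because mean firing-rate modulation and state-driven
#' covariability are empirically dissociable:
#'
#' * `gain_attended` / `gain_unattended` are the *condition mean* gains: the
#'   average attentional gain while the receptive-field stimulus is cued
#'   (Attend In) or the opposite stimulus is cued (Attend Out). Their gap
#'   sets the mean rate difference between conditions (a few percent).
#' * `ab_state_separation` is the distance between the two latent states the
#'   subject switches between when both stimuli are relevant (Attend Both):
#'   the realized gain is the AI/AO midpoint plus or minus half this
#'   separation. It sets the size of the attention-driven shared variability
#'   and may exceed the condition-mean gap.
#'
#' In the Attend Both condition the state starts at random
#' (`ab_state_prior`) and switches as a telegraph process with exponential
#' dwell times of mean `1/within_trial_switch_hz` (default 4 Hz, i.e. a
#' switch roughly every 250 ms). With probability `p_attend_both` an AB trial
#' is instead spent attending both stimuli at the midpoint gain with no
#' switching, emulating subjects that cover nearby stimuli simultaneously.
#' `focused_state_sd` is the trial-to-trial jitter of the attentional state,
#' shared by the population and present in every condition.
#'
#' @param gain_attended,gain_unattended condition mean gains (attended >=
#'   unattended > 0).
#' @param within_trial_switch_hz switching rate in the AB condition (Hz).
#' @param focused_state_sd SD of the shared trial-to-trial state jitter.
#' @param ab_state_separation gain distance between the two AB states.
#' @param ab_state_prior probability of starting an AB trial attending the
#'   receptive-field stimulus.
#' @param p_attend_both probability that an AB trial is spent attending both
#'   stimuli simultaneously (no switching).
#' @return An object of class `attention_model_params`.
#' @export
attention_model_params <- function(gain_attended = 1.03,
                                   gain_unattended = 0.98,
                                   within_trial_switch_hz = 4,
                                   focused_state_sd = 0.12,
                                   ab_state_separation = 0.5,
                                   ab_state_prior = 0.5,
                                   p_attend_both = 0) {
  stopifnot(gain_attended >= gain_unattended, gain_unattended > 0,
            within_trial_switch_hz >= 0, focused_state_sd >= 0,
            ab_state_separation >= 0,
            ab_state_prior >= 0, ab_state_prior <= 1,
            p_attend_both >= 0, p_attend_both <= 1)
  structure(as.list(environment()), class = "attention_model_params")
}

#' Construct a roster of synthetic orientation-tuned units
#'
#' Units have von Mises tuning on the doubled angle, a 50 ms response
#' latency, and one of three attentional coupling classes: pure gain (the
#' state multiplies the tuned drive), pure offset (the state adds to the
#' baseline), or mixed, in proportions matching the attention literature
#' (roughly 32% gain, 20% offset, remainder mixed). Depths sit on the 60 um
#' channel grid relative to the first layer-5 channel. Baselines and
#' amplitudes are drawn so that the population mean rate under the dynamic
#' stimulus is near 22 spikes/s.
#'
#' @param n_units number of units.
#' @param session_seed integer RNG stream id.
#' @param class_probs probabilities of (gain, offset, mixed) coupling.
#' @param common_noise_loading loading (spikes/s) on the fast shared noise
#'   process, identical across units by default.
#' @return `data.frame` with one row per unit.
#' @export
make_unit_roster <- function(n_units = 10L, session_seed = 0L,
                             class_probs = c(gain = 0.32, offset = 0.20, mixed = 0.48),
                             common_noise_loading = 1.5) {
  with_seed(derive_seed(session_seed, 577L), {
    cls <- sample(names(class_probs), n_units, replace = TRUE, prob = class_probs)
    data.frame(
      unit = seq_len(n_units),
      pref_deg = (seq_len(n_units) - 1L) * (180 / n_units) + runif(n_units, 0, 5),
      kappa = runif(n_units, 1.2, 1.9),
      baseline = runif(n_units, 5, 11),
      amplitude = runif(n_units, 30, 46),
      latency_ms = rep(50, n_units),
      coupling_class = cls,
      gain_coupling = ifelse(cls == "gain", 1, ifelse(cls == "mixed", 0.6, 0)),
      offset_coupling = ifelse(cls == "offset", 25, ifelse(cls == "mixed", 10, 0)),
      common_noise_loading = rep(common_noise_loading, n_units),
      depth_um = (sample(seq(-12L, 7L), n_units, replace = TRUE)) * 60,
      stringsAsFactors = FALSE
    )
  })
}

#' Sample the latent attention state for one trial
#'
#' Returns the per-frame latent state and attention variable `a(t)`
#' (realized gain minus one, including the shared trial jitter). In AI/AO
#' the state is constant within the trial; in AB the state follows a
#' telegraph process between the attend-RF and attend-away states unless the
#' trial is an attend-both trial. Consumes the caller's RNG stream.
#'
#' @param condition `"AI"`, `"AB"` or `"AO"`.
#' @param n_frames number of stimulus frames to cover.
#' @param params an [attention_model_params()] object.
#' @param frame_ms frame duration (ms).
#' @return List with `state` (per-frame, `"rf"`, `"away"` or `"both"`), `a`
#'   (per-frame attention variable), and `jitter` (the trial's shared state
#'   jitter).
#' @export
sample_attention_state <- function(condition, n_frames,
                                   params = attention_model_params(),
                                   frame_ms = 10) {
  jit <- rnorm(1, 0, params$focused_state_sd)
  mid <- (params$gain_attended + params$gain_unattended) / 2
  if (condition == "AI") {
    state <- rep("rf", n_frames)
    a <- rep(params$gain_attended - 1 + jit, n_frames)
  } else if (condition == "AO") {
    state <- rep("away", n_frames)
    a <- rep(params$gain_unattended - 1 + jit, n_frames)
  } else if (condition == "AB") {
    if (runif(1) < params$p_attend_both) {
      state <- rep("both", n_frames)
      a <- rep(mid - 1 + jit, n_frames)
    } else {
      cur <- runif(1) < params$ab_state_prior  # TRUE = attending RF stimulus
      state <- character(n_frames)
      hz <- params$within_trial_switch_hz
      f <- 1L
      while (f <= n_frames) {
        dwell_frames <- if (hz > 0)
          max(1L, as.integer(ceiling(rexp(1, hz) * 1000 / frame_ms)))
        else n_frames
        to <- min(n_frames, f + dwell_frames - 1L)
        state[f:to] <- if (cur) "rf" else "away"
        cur <- !cur
        f <- to + 1L
      }
      a <- mid - 1 + ifelse(state == "rf", 1, -1) * params$ab_state_separation / 2 + jit
    }
  } else stop("unknown condition: ", condition)
  list(state = state, a = a, jitter = jit)
}

# von Mises orientation tuning on the doubled angle, peak value = 1
vm_bump <- function(theta_deg, pref_deg, kappa) {
  exp(kappa * (cos(2 * (theta_deg - pref_deg) * pi / 180) - 1))
}

# per-unit lookup table of tuned drive (spikes/s) for the 36 grid orientations
tuning_table <- function(units, params = stimulus_params()) {
  vapply(seq_len(nrow(units)), function(u) {
    units$amplitude[u] * vm_bump(params$grid, units$pref_deg[u], units$kappa[u])
  }, numeric(params$n_orientations))
}

#' Simulate spike trains for one trial
#'
#' Each unit fires as an inhomogeneous Poisson process whose rate is
#' piecewise constant over 10 ms stimulus frames:
#' `lambda_i(f) = drift * [baseline_i + offset_i * a(f)
#'   + (1 + gain_i * a(f)) * amplitude_i * VM(theta(f - latency_i)) + l_i * z(f)]+`
#' where `a(f)` is the latent attention variable, `z(f)` an optional fast
#' shared noise process, and `[.]+` denotes rectification at zero. Spike
#' counts per frame are Poisson and spike times uniform within the frame
#' (exact inhomogeneous Poisson for a piecewise-constant rate). A `pre_ms`
#' fixation interval at the spontaneous baseline rate is prepended with
#' negative spike times. Consumes the caller's RNG stream.
#'
#' @param codes frame orientation codes (0-based grid indices) for the trial.
#' @param units roster from [make_unit_roster()].
#' @param a per-frame attention variable (from [sample_attention_state()]).
#' @param drift multiplicative slow-drift factor for the trial's block.
#' @param z per-frame shared noise (unit variance), or `NULL`.
#' @param params a [stimulus_params()] object.
#' @param pre_ms length of the pre-stimulus fixation interval (ms).
#' @param tune_tab optional precomputed [36 x n_units] tuned-drive table.
#' @return `data.frame(unit, time_ms)`, times relative to stimulus onset.
#' @export
simulate_spike_trains <- function(codes, units, a, drift = 1, z = NULL,
                                  params = stimulus_params(), pre_ms = 0,
                                  tune_tab = NULL) {
  if (is.null(tune_tab)) tune_tab <- tuning_table(units, params)
  nf <- length(codes)
  nu <- nrow(units)
  stopifnot(length(a) == nf)
  dt <- params$frame_ms / 1000
  lat_f <- as.integer(round(units$latency_ms / params$frame_ms))
  mean_drive <- colMeans(tune_tab)
  # tuned drive per frame, shifted by each unit's latency; frames before the
  # latency see the orientation-averaged drive (stationary stand-in)
  drive <- matrix(rep(mean_drive, each = nf), nf, nu)
  for (u in seq_len(nu)) {
    if (lat_f[u] < nf) {
      idx <- seq_len(nf - lat_f[u])
      drive[idx + lat_f[u], u] <- tune_tab[codes[idx] + 1L, u]
    }
  }
  A <- matrix(a, nf, nu)
  rate <- matrix(units$baseline, nf, nu, byrow = TRUE) +
    A * matrix(units$offset_coupling, nf, nu, byrow = TRUE) +
    (1 + A * matrix(units$gain_coupling, nf, nu, byrow = TRUE)) * drive
  if (!is.null(z))
    rate <- rate + matrix(z, nf, nu) * matrix(units$common_noise_loading, nf, nu, byrow = TRUE)
  rate <- drift * pmax(rate, 0)
  counts <- matrix(rpois(nf * nu, rate * dt), nf, nu)
  tot <- sum(counts)
  if (pre_ms > 0) {
    pre_f <- as.integer(pre_ms / params$frame_ms)
    pre_counts <- matrix(rpois(pre_f * nu,
                               rep(drift * units$baseline * dt, each = pre_f)),
                         pre_f, nu)
  } else pre_counts <- NULL
  expand <- function(cnt, offset_ms) {
    idx <- which(cnt > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    k <- cnt[idx]
    data.frame(
      unit = rep(units$unit[idx[, 2L]], k),
      time_ms = rep((idx[, 1L] - 1L) * params$frame_ms + offset_ms, k) +
        runif(sum(k), 0, params$frame_ms)
    )
  }
  out <- rbind(if (!is.null(pre_counts)) expand(pre_counts, -pre_ms), expand(counts, 0))
  if (is.null(out)) data.frame(unit = integer(0), time_ms = numeric(0)) else out
}

# AR(1) shared noise per frame with ~20 ms correlation time, unit variance
simulate_common_noise <- function(n_frames, frame_ms = 10, tau_ms = 20) {
  phi <- exp(-frame_ms / tau_ms)
  z <- numeric(n_frames)
  z[1L] <- rnorm(1)
  if (n_frames > 1L)
    for (f in 2L:n_frames) z[f] <- phi * z[f - 1L] + sqrt(1 - phi^2) * rnorm(1)
  z
}

#' Behavioral model parameters
#'
#' Detection probability is logistic in coherence with a lower threshold
#' when the changed stimulus is in the attended state at CP onset. False
#' alarms arise from a constant hazard during the ZCP. Reaction times on
#' hits are drawn from a scaled Beta distribution on the legal response
#' window (100 ms after CP onset to 200 ms after CP end).
#'
#' @param threshold_attended,threshold_unattended logistic 50% points
#'   (coherence frames) for attended / unattended changes.
#' @param slope logistic slope (1/frame).
#' @param fa_hazard_hz false-alarm hazard during the ZCP (1/s).
#' @param lockout_ms response lockout after CP onset.
#' @param rt_shape1,rt_shape2 Beta shape parameters of the reaction-time
#'   distribution on the response window.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(threshold_attended = 3.5,
                            threshold_unattended = 5.5,
                            slope = 0.9,
                            fa_hazard_hz = 0.22,
                            lockout_ms = 100,
                            rt_shape1 = 2.2, rt_shape2 = 1.6) {
  stopifnot(slope > 0, fa_hazard_hz >= 0, threshold_unattended >= threshold_attended)
  structure(as.list(environment()), class = "behavior_params")
}

#' Median of the generative reaction-time distribution
#'
#' Closed form for the median reaction time (ms after CP onset) implied by
#' [behavior_params()], used as the oracle in recovery checks.
#' @param params a [behavior_params()] object.
#' @param window_ms length of the legal response window beyond the lockout.
#' @return Median RT in ms after CP onset.
#' @export
behavior_rt_median <- function(params = behavior_params(), window_ms = 400) {
  params$lockout_ms + qbeta(0.5, params$rt_shape1, params$rt_shape2) * window_ms
}

#' Simulate the behavioral response for one trial
#'
#' Draws a false-alarm time from the constant ZCP hazard and, on change
#' trials that survive it, a Bernoulli detection with probability logistic
#' in coherence (threshold depending on whether the changed stimulus is
#' attended at CP onset). Returns the saccade event (side and time), not the
#' outcome: outcome classification is left to [classify_outcome()] so the
#' analysis path is exercised end to end. Consumes the caller's RNG stream.
#'
#' @param trial one row of a session schedule (`zcp_s`, `coherence`,
#'   `change_side`, `is_catch`).
#' @param state_at_cp latent state at CP onset (`"rf"`, `"away"`, `"both"`;
#'   ignored for catch trials).
#' @param params a [behavior_params()] object.
#' @param rf_side which stimulus covers the receptive fields.
#' @param stim a [stimulus_params()] object.
#' @return List with `saccade_side` (`"left"`, `"right"` or `"none"`) and
#'   `saccade_ms` (time relative to stimulus onset, `NA` if none).
#' @export
simulate_behavior <- function(trial, state_at_cp, params = behavior_params(),
                              rf_side = "left", stim = stimulus_params()) {
  cp_ms <- stim$cp_frames * stim$frame_ms
  zcp_ms <- trial$zcp_s * 1000
  dur_ms <- zcp_ms + cp_ms + stim$post_cp_ms
  fa_ms <- if (params$fa_hazard_hz > 0) rexp(1, params$fa_hazard_hz) * 1000 else Inf
  fa_limit <- if (trial$is_catch) dur_ms else zcp_ms + params$lockout_ms
  if (fa_ms < fa_limit) {
    return(list(saccade_side = sample(c("left", "right"), 1L), saccade_ms = fa_ms))
  }
  if (trial$is_catch) return(list(saccade_side = "none", saccade_ms = NA_real_))
  attended <- state_at_cp == "both" ||
    (state_at_cp == "rf" && trial$change_side == rf_side) ||
    (state_at_cp == "away" && trial$change_side != rf_side)
  thr <- if (attended) params$threshold_attended else params$threshold_unattended
  if (runif(1) < plogis(params$slope * (trial$coherence - thr))) {
    window <- cp_ms + stim$post_cp_ms - params$lockout_ms
    rt <- params$lockout_ms + rbeta(1, params$rt_shape1, params$rt_shape2) * window
    list(saccade_side = trial$change_side, saccade_ms = zcp_ms + rt)
  } else {
    list(saccade_side = "none", saccade_ms = NA_real_)
  }
}

#' @importFrom stats rbeta
NULL

#' Eye-trace generator parameters
#'
#' @param rate_hz sampling rate of the gaze signal.
#' @param jitter_sd SD (deg) of fixational jitter (kept sub-threshold).
#' @param event_rate_hz rate of planted microsaccades.
#' @param amp_range amplitude range (deg) of planted microsaccades.
#' @param dur_range_ms duration range (ms); durations are capped so that the
#'   planted peak 10 ms displacement exceeds the 0.1 deg detection criterion
#'   with margin, otherwise the smallest slow saccades would be invisible to
#'   any velocity-threshold detector.
#' @return An object of class `eye_params`.
#' @export
eye_params <- function(rate_hz = 1000, jitter_sd = 0.01,
                       event_rate_hz = 1.5,
                       amp_range = c(0.2, 1.0), dur_range_ms = c(10, 30)) {
  structure(as.list(environment()), class = "eye_params")
}

#' Simulate a 2-D gaze trace with planted microsaccades
#'
#' Gaussian fixational jitter (AR(1), sub-threshold by construction) plus
#' planted microsaccades with half-cosine displacement profiles and logged
#' directions. The ground-truth event list is returned for detector
#' validation. Consumes the caller's RNG stream.
#'
#' @param duration_ms trace duration.
#' @param params an [eye_params()] object.
#' @param n_events number of planted events; default draws from
#'   `event_rate_hz`.
#' @return List with `t_ms`, `x`, `y` (deg) and `events`
#'   (`data.frame(onset_ms, duration_ms, amplitude_deg, direction_deg)`).
#' @export
simulate_eye_trace <- function(duration_ms, params = eye_params(),
                               n_events = NULL) {
  dt <- 1000 / params$rate_hz
  n <- as.integer(duration_ms / dt)
  t_ms <- (seq_len(n) - 1L) * dt
  ar <- function() {
    e <- numeric(n); e[1L] <- rnorm(1, 0, params$jitter_sd)
    for (i in seq_len(n - 1L))
      e[i + 1L] <- 0.9 * e[i] + sqrt(1 - 0.81) * rnorm(1, 0, params$jitter_sd)
    e
  }
  x <- ar(); y <- ar()
  if (is.null(n_events)) n_events <- rpois(1, params$event_rate_hz * duration_ms / 1000)
  events <- NULL
  if (n_events > 0) {
    # space onsets so events (plus margin) never overlap
    slot <- duration_ms / n_events
    onset <- (seq_len(n_events) - 1L) * slot + runif(n_events, 50, max(51, slot - 100))
    amp <- runif(n_events, params$amp_range[1L], params$amp_range[2L])
    dur <- runif(n_events, params$dur_range_ms[1L], params$dur_range_ms[2L])
    dur <- pmin(dur, 10 * amp / 0.15)  # keep peak 10 ms displacement >= 0.15 deg
    dir <- runif(n_events, 0, 360)
    for (i in seq_len(n_events)) {
      i0 <- findInterval(onset[i], t_ms)
      k <- max(2L, as.integer(dur[i] / dt))
      if (i0 + k > n) next
      prof <- amp[i] * (1 - cos(pi * seq_len(k) / k)) / 2  # half-cosine ramp
      dx <- prof * cos(dir[i] * pi / 180); dy <- prof * sin(dir[i] * pi / 180)
      x[(i0 + 1L):(i0 + k)] <- x[(i0 + 1L):(i0 + k)] + dx
      y[(i0 + 1L):(i0 + k)] <- y[(i0 + 1L):(i0 + k)] + dy
      if (i0 + k < n) {
        x[(i0 + k + 1L):n] <- x[(i0 + k + 1L):n] + dx[k]
        y[(i0 + k + 1L):n] <- y[(i0 + k + 1L):n] + dy[k]
      }
    }
    events <- data.frame(onset_ms = onset, duration_ms = dur,
                         amplitude_deg = amp, direction_deg = dir)
  }
  list(t_ms = t_ms, x = x, y = y,
       events = events %||% data.frame(onset_ms = numeric(0), duration_ms = numeric(0),
                                       amplitude_deg = numeric(0), direction_deg = numeric(0)))
}

#' Simulate stimulus-evoked laminar LFPs with a known sink
#'
#' A dipolar potential whose second spatial derivative (the CSD) has its
#' sink extremum at `sink_channel`, driven by a damped-oscillation response
#' after stimulus onset, plus spatially smooth Gaussian noise. Consumes the
#' caller's RNG stream.
#'
#' @param n_channels number of channels (60 um spacing assumed).
#' @param sink_channel channel index of the planted sink.
#' @param duration_ms,onset_ms trace length and response onset.
#' @param width_ch spatial width (channels) of the dipole.
#' @param noise_sd SD of the additive noise (same units as the signal).
#' @return `channels x time` voltage matrix with a `time_ms` attribute.
#' @export
simulate_lfp <- function(n_channels = 32L, sink_channel = 20L,
                         duration_ms = 200, onset_ms = 20,
                         width_ch = 2, noise_sd = 0.02) {
  t_ms <- seq_len(duration_ms) - 1
  a <- ifelse(t_ms > onset_ms,
              exp(-(t_ms - onset_ms) / 60) * sin(2 * pi * (t_ms - onset_ms) / 100), 0)
  g <- exp(-((seq_len(n_channels) - sink_channel)^2) / (2 * width_ch^2))
  v <- -outer(g, a)
  if (noise_sd > 0) {
    noise <- matrix(rnorm(n_channels * duration_ms, 0, noise_sd),
                    n_channels, duration_ms)
    k <- gaussian_kernel(1.5)
    noise <- apply(noise, 2L, smooth_replicate, kernel = k)  # smooth over depth
  } else noise <- 0
  out <- v + noise
  attr(out, "time_ms") <- t_ms
  out
}
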