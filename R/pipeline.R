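#' Session configuration
#'
#' Bundles every parameter of a simulated recording session: RNG seed,
#' stimulus constants, attention-model and behavioral parameters, the unit
#' roster size, block layout, and stimulus eccentricity. By default the
#' probability that the subject attends both stimuli simultaneously in the
#' Attend-Both condition decreases linearly with horizontal eccentricity
#' (nearby stimuli are easy to cover with one attentional field; distant
#' stimuli force switching), which is the mechanism behind the
#' eccentricity trend of the correlation contrast.
#'
#' @param session_seed integer seed; every random stream of the session is
#'   derived from it.
#' @param n_units number of simultaneously recorded units.
#' @param n_blocks number of attention blocks (multiple of 3).
#' @param base_coherences the session's five base coherence levels.
#' @param rf_side stimulus overlying the recorded receptive fields.
#' @param eccentricity_deg horizontal eccentricity of the stimuli.
#' @param attention [attention_model_params()]; if `NULL`, defaults with
#'   `p_attend_both` tied to eccentricity as above.
#' @param behavior [behavior_params()].
#' @param stim [stimulus_params()].
#' @param drift_sd per-block SD of the multiplicative slow drift
#'   (log-normal random walk).
#' @param pre_ms pre-stimulus fixation interval simulated at baseline rate.
#' @param trials_per_block trial pool per block (blocks advance after 60
#'   counted hit/miss trials).
#' @return List of class `session_config`.
#' @export
session_config <- function(session_seed = 1L, n_units = 10L, n_blocks = 6L,
                           base_coherences = c(1L, 3L, 5L, 7L, 9L),
                           rf_side = "left", eccentricity_deg = 8,
                           attention = NULL, behavior = behavior_params(),
                           stim = stimulus_params(), drift_sd = 0.05,
                           pre_ms = 300, trials_per_block = 130L) {
  if (is.null(attention)) {
    p_both <- clamp(1 - (eccentricity_deg - 3) / 5.9, 0, 1)
    attention <- attention_model_params(p_attend_both = p_both)
  }
  structure(list(
    session_seed = as.integer(session_seed), n_units = as.integer(n_units),
    n_blocks = as.integer(n_blocks), base_coherences = base_coherences,
    rf_side = rf_side, eccentricity_deg = eccentricity_deg,
    attention = attention, behavior = behavior, stim = stim,
    drift_sd = drift_sd, pre_ms = pre_ms,
    trials_per_block = as.integer(trials_per_block)
  ), class = "session_config")
}

#' Simulate a complete recording session
#'
#' Builds the trial schedule, generates the five repeatable orientation
#' streams, samples the latent attention state of every trial, simulates
#' population spike trains and the behavioral response, classifies
#' outcomes, and applies the block-advance rule (a block ends after 60
#' counted hit/miss trials). The entire session is a deterministic function
#' of the configuration.
#'
#' @param config a [session_config()].
#' @return List of class `session_bundle`: `config`, `trials` (schedule
#'   plus `outcome`, `rt_ms`, `counted`), `spikes`
#'   (`data.frame(unit, trial, time_ms)`), `units`, and `ground_truth`
#'   (per-trial state jitter, state at CP onset, mean attention variable in
#'   the first second).
#' @export
simulate_session <- function(config = session_config()) {
  stim <- config$stim
  with_seed(derive_seed(config$session_seed, 1L), {
    schedule <- build_session_schedule(list(
      base_coherences = config$base_coherences, rf_side = config$rf_side,
      n_blocks = config$n_blocks, trials_per_block = config$trials_per_block,
      stim_params = stim))
    units <- make_unit_roster(config$n_units, config$session_seed)
    tune_tab <- tuning_table(units, stim)
    drift <- exp(cumsum(rnorm(config$n_blocks, 0, config$drift_sd)))
    drift <- drift / mean(drift)
    max_frames <- max(schedule$zcp_frames) + stim$cp_frames +
      as.integer(stim$post_cp_ms / stim$frame_ms)
    base_seq <- list()
    for (s in 0:(stim$n_seeds - 1L)) for (sd_ in c("left", "right"))
      base_seq[[paste(s, sd_)]] <- generate_orientation_sequence(
        s, max_frames, stim, sd_, session_seed = config$session_seed)
    counted_target <- attr(schedule, "counted_per_block")
    post_f <- as.integer(stim$post_cp_ms / stim$frame_ms)
    spk <- list(); keep <- logical(nrow(schedule))
    outcome <- character(nrow(schedule)); rt <- rep(NA_real_, nrow(schedule))
    gt_jit <- gt_mean_a <- rep(NA_real_, nrow(schedule))
    gt_cp_state <- rep(NA_character_, nrow(schedule))
    for (b in seq_len(config$n_blocks)) {
      rows <- which(schedule$block == b)
      counted <- 0L
      for (i in rows) {
        if (counted >= counted_target) break
        tr <- schedule[i, ]
        keep[i] <- TRUE
        nf <- tr$zcp_frames + stim$cp_frames + post_f
        rf_seq <- base_seq[[paste(tr$seed_id, config$rf_side)]]
        codes <- rf_seq$codes[seq_len(nf)]
        if (!tr$is_catch && tr$change_side == config$rf_side) {
          emb <- embed_coherent_period(
            structure(list(codes = codes, frames = codes * stim$orientation_spacing,
                           seed_id = tr$seed_id, side = config$rf_side,
                           signal_mask = rep(FALSE, nf), cp_start_frame = NA_integer_,
                           zcp_frames = nf, params = stim),
                      class = "orientation_sequence"),
            tr$coherence, tr$zcp_frames)
          codes <- emb$codes
        }
        st <- sample_attention_state(tr$condition, nf, config$attention,
                                     stim$frame_ms)
        z <- simulate_common_noise(nf, stim$frame_ms)
        sp <- simulate_spike_trains(codes, units, st$a, drift[b], z,
                                    stim, config$pre_ms, tune_tab)
        sp$trial <- tr$trial
        spk[[length(spk) + 1L]] <- sp
        cp_state <- st$state[min(nf, tr$zcp_frames + 1L)]
        beh <- simulate_behavior(tr, cp_state, config$behavior,
                                 config$rf_side, stim)
        outcome[i] <- classify_outcome(tr, beh$saccade_side, beh$saccade_ms,
                                       stim, config$behavior$lockout_ms)
        if (outcome[i] == "hit") rt[i] <- beh$saccade_ms - tr$zcp_s * 1000
        if (outcome[i] %in% c("hit", "miss")) counted <- counted + 1L
        wf <- min(nf, 100L)
        gt_jit[i] <- st$jitter; gt_cp_state[i] <- cp_state
        gt_mean_a[i] <- mean(st$a[seq_len(wf)])
      }
    }
    trials <- schedule[keep, , drop = FALSE]
    trials$outcome <- outcome[keep]
    trials$rt_ms <- rt[keep]
    spikes <- as.data.frame(data.table::rbindlist(spk))
    structure(list(
      config = config, trials = trials,
      spikes = spikes[, c("unit", "trial", "time_ms")],
      units = units,
      ground_truth = data.frame(trial = schedule$trial[keep],
                                jitter = gt_jit[keep],
                                cp_state = gt_cp_state[keep],
                                mean_a_1s = gt_mean_a[keep])
    ), class = "session_bundle")
  })
}

#' Select analysis trials
#'
#' The shared trial mask for all spike-count analyses: correct trials
#' (hits and correct rejections) whose zero-coherence period covers the
#' analysis window, so that counts come from identical stimuli before any
#' coherence change or behavioral response.
#'
#' @param trials session trial table with `outcome` and `zcp_s`.
#' @param window_ms analysis window from stimulus onset.
#' @return The qualifying rows of `trials`.
#' @export
select_analysis_trials <- function(trials, window_ms = 1000) {
  trials[trials$outcome %in% c("hit", "correct_rejection") &
           trials$zcp_s * 1000 >= window_ms, , drop = FALSE]
}

# spike counts of every unit in [0, window_ms) for the given trials
count_window <- function(spikes, trials, units, window_ms) {
  dt <- data.table::as.data.table(spikes)
  dt <- dt[trial %in% trials$trial & time_ms >= 0 & time_ms < window_ms]
  cnt <- dt[, .N, by = .(unit, trial)]
  grid <- data.table::CJ(unit = units, trial = trials$trial)
  cnt <- merge(grid, cnt, by = c("unit", "trial"), all.x = TRUE)
  cnt[is.na(N), N := 0L]
  meta <- data.table::as.data.table(
    trials[, c("trial", "condition", "seed_id", "block")])
  out <- merge(cnt, meta, by = "trial")
  data.table::setnames(out, "N", "count")
  as.data.frame(out)
}

#' Run the analysis chain on a session
#'
#' Applies the shared trial selection, then the requested analyses:
#' `"variability"` (block-wise z-scored pairwise correlations and Fano
#' factors per condition), `"behavior"` (psychometric thresholds and the
#' outcome summary), `"timescale"` (session-mean r_CCG curves), and
#' `"tuning"` (per-unit tuning, responsiveness, and inclusion screening).
#'
#' @param bundle a [simulate_session()] result.
#' @param window_ms spike-count window (200 or 1000 ms).
#' @param analyses subset of `c("variability", "behavior", "timescale",
#'   "tuning")`.
#' @param rccg_tau lag grid (ms) for the reported r_CCG curves.
#' @param n_boot bootstrap resamples for psychometric CIs (0 to skip).
#' @param n_perm permutations for the tuning test.
#' @return List of class `session_results` with elements per analysis plus
#'   `rsc` (per-condition mean correlation), `contrast`, and
#'   `eccentricity_deg`.
#' @export
run_session_analysis <- function(bundle, window_ms = 1000,
                                 analyses = c("variability", "behavior",
                                              "timescale"),
                                 rccg_tau = c(50, 100, 200, 400, 700, 1000),
                                 n_boot = 0L, n_perm = 200L) {
  res <- list(session_seed = bundle$config$session_seed,
              eccentricity_deg = bundle$config$eccentricity_deg,
              window_ms = window_ms)
  sel <- select_analysis_trials(bundle$trials, window_ms)
  units <- bundle$units$unit
  if ("variability" %in% analyses) {
    counts <- count_window(bundle$spikes, sel, units, window_ms)
    z <- blockwise_zscore(counts)
    pr <- pairwise_rsc(z)
    res$pairs <- pr
    res$rsc <- tapply(pr$r_sc, pr$condition, mean, na.rm = TRUE)
    res$fano <- fano_factor(counts)
    if (all(c("AI", "AB", "AO") %in% names(res$rsc)))
      res$contrast <- unname(res$rsc["AB"] -
                               (res$rsc["AI"] + res$rsc["AO"]) / 2)
  }
  if ("behavior" %in% analyses) {
    res$psychometric <- fit_psychometric(bundle$trials, n_boot = n_boot)
    res$behavior_summary <- session_behavior_summary(bundle$trials)
  }
  if ("timescale" %in% analyses) {
    hits <- sel[sel$outcome == "hit", , drop = FALSE]
    res$rccg <- session_rccg(bundle$spikes, hits, units, window_ms,
                             tau_subset = rccg_tau)
  }
  if ("tuning" %in% analyses) {
    zf <- sel
    tun <- lapply(units, function(u) {
      sp <- split(bundle$spikes$time_ms[bundle$spikes$unit == u],
                  factor(bundle$spikes$trial[bundle$spikes$unit == u],
                         levels = zf$trial))
      codes <- lapply(seq_len(nrow(zf)), function(i) {
        s <- generate_orientation_sequence(
          zf$seed_id[i], zf$zcp_frames[i], bundle$config$stim,
          bundle$config$rf_side, session_seed = bundle$config$session_seed)
        s$codes
      })
      tc <- estimate_tuning(sp, codes, bundle$config$stim)
      pre <- vapply(sp, function(tt) sum(tt >= -300 & tt < 0), numeric(1L))
      post <- vapply(sp, function(tt) sum(tt >= 0 & tt < 300), numeric(1L))
      list(tc = tc, p_tuned = tuning_significance(tc, n_perm),
           p_responsive = visual_responsiveness(pre, post))
    })
    names(tun) <- units
    res$tuning <- tun
  }
  class(res) <- "session_results"
  res
}

#' Session inclusion screen
#'
#' A session enters the dataset if it has at least `min_units` single units
#' that are visually responsive and significantly orientation tuned, and at
#' least `min_seeds` valid stimulus seeds, where a seed is invalid if any
#' attention condition has fewer than three correct trials of sufficient
#' zero-coherence length for that seed.
#'
#' @param trials session trial table (with outcomes).
#' @param unit_quality `data.frame(unit, responsive, tuned)` of logicals.
#' @param window_ms analysis window defining sufficient ZCP length.
#' @param min_units,min_seeds,min_trials inclusion thresholds.
#' @return List with `include`, `reasons`, `n_qualifying_units`,
#'   `n_valid_seeds`.
#' @export
session_inclusion <- function(trials, unit_quality, window_ms = 1000,
                              min_units = 10L, min_seeds = 3L,
                              min_trials = 3L) {
  nq <- sum(unit_quality$responsive & unit_quality$tuned)
  sel <- select_analysis_trials(trials, window_ms)
  seeds <- sort(unique(trials$seed_id))
  valid <- vapply(seeds, function(s) {
    tab <- table(factor(sel$condition[sel$seed_id == s],
                        levels = c("AI", "AB", "AO")))
    all(tab >= min_trials)
  }, logical(1L))
  reasons <- character(0)
  if (nq < min_units)
    reasons <- c(reasons, sprintf("only %d qualifying units (need %d)",
                                  nq, min_units))
  if (sum(valid) < min_seeds)
    reasons <- c(reasons, sprintf("only %d valid seeds (need %d)",
                                  sum(valid), min_seeds))
  list(include = length(reasons) == 0L, reasons = reasons,
       n_qualifying_units = nq, n_valid_seeds = sum(valid))
}

#' Simulate and analyze a batch of sessions
#'
#' Runs [simulate_session()] and [run_session_analysis()] over a batch with
#' eccentricities spanning the recorded range (3.7-8.9 degrees), as in a
#' multi-session experiment. Returns per-session summaries assembled for
#' the session-level statistics: psychometric thresholds, mean pairwise
#' correlations, correlation contrasts, and mean r_CCG curves per
#' condition.
#'
#' @param n_sessions number of sessions.
#' @param base_seed integer; session seeds are derived from it.
#' @param window_ms spike-count window.
#' @param analyses forwarded to [run_session_analysis()].
#' @param eccentricities optional vector of per-session eccentricities.
#' @param ... further arguments to [session_config()].
#' @return List with `thresholds` (sessions x AI/AB/AO), `rsc`
#'   (sessions x condition), `contrast`, `eccentricity_deg`, and `rccg`
#'   (mean across sessions, `data.frame(condition, tau_ms, r_ccg)`).
#' @export
run_session_study <- function(n_sessions = 30L, base_seed = 1L,
                              window_ms = 1000,
                              analyses = c("variability", "behavior",
                                           "timescale"),
                              eccentricities = NULL, ...) {
  ecc <- eccentricities %||% seq(3.7, 8.9, length.out = n_sessions)
  conds <- c("AI", "AB", "AO")
  thr <- rsc <- matrix(NA_real_, n_sessions, 3L,
                       dimnames = list(NULL, conds))
  contrast <- rep(NA_real_, n_sessions)
  rccg_list <- list()
  for (i in seq_len(n_sessions)) {
    cfg <- session_config(session_seed = derive_seed(base_seed, 1000L + i),
                          eccentricity_deg = ecc[i], ...)
    bundle <- simulate_session(cfg)
    r <- run_session_analysis(bundle, window_ms, analyses)
    if (!is.null(r$psychometric))
      thr[i, ] <- r$psychometric$threshold_50[
        match(conds, r$psychometric$condition)]
    if (!is.null(r$rsc)) {
      rsc[i, ] <- r$rsc[conds]
      contrast[i] <- r$contrast %||% NA_real_
    }
    if (!is.null(r$rccg)) {
      r$rccg$session <- i
      rccg_list[[length(rccg_list) + 1L]] <- r$rccg
    }
  }
  rccg <- rccg_sessions <- NULL
  if (length(rccg_list)) {
    rccg_sessions <- do.call(rbind, rccg_list)
    rccg <- aggregate(r_ccg ~ condition + tau_ms, rccg_sessions, mean)
  }
  list(thresholds = thr, rsc = rsc, contrast = contrast,
       eccentricity_deg = ecc, rccg = rccg, rccg_sessions = rccg_sessions)
}
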