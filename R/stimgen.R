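#' Stimulus parameters for the orientation change-detection task
#'
#' Container for the constants of the dynamic orientation-noise stimulus:
#' 36 orientations spaced 5 degrees apart (period 180), 10 ms frames, a
#' zero-coherence period (ZCP) whose duration follows a bounded exponential
#' (minimum 0.01 s, mean 2.17 s, maximum 5 s), a 300 ms coherent period
#' (CP, 30 frames) followed by 200 ms of ZCP, orthogonal signal orientations
#' for the left (135 deg) and right (45 deg) stimulus, five repeatable
#' stimulus seeds per session, and a 10% catch-trial fraction.
#'
#' @param n_orientations number of orientations on the grid.
#' @param orientation_spacing grid spacing in degrees.
#' @param frame_ms frame duration in ms.
#' @param cp_frames number of frames in the coherent period.
#' @param post_cp_ms ZCP tail after the CP, in ms.
#' @param zcp_min_s,zcp_mean_s,zcp_max_s ZCP duration bounds and mean (s).
#' @param signal_orientation_left,signal_orientation_right signal
#'   orientations in degrees for the two stimuli.
#' @param n_seeds number of repeatable stimulus seeds per session.
#' @param catch_fraction probability that a trial has no coherent period.
#' @return An object of class `stimulus_params`.
#' @export
stimulus_params <- function(n_orientations = 36L,
                            orientation_spacing = 5,
                            frame_ms = 10,
                            cp_frames = 30L,
                            post_cp_ms = 200,
                            zcp_min_s = 0.01,
                            zcp_mean_s = 2.17,
                            zcp_max_s = 5,
                            signal_orientation_left = 135,
                            signal_orientation_right = 45,
                            n_seeds = 5L,
                            catch_fraction = 0.10) {
  stopifnot(n_orientations * orientation_spacing == 180,
            zcp_min_s >= 0.01 - 1e-12, zcp_max_s <= 5 + 1e-12,
            zcp_min_s < zcp_mean_s, zcp_mean_s < zcp_max_s,
            catch_fraction >= 0, catch_fraction <= 1, n_seeds >= 1)
  grid <- (seq_len(n_orientations) - 1L) * orientation_spacing
  if (!(signal_orientation_left %in% grid) ||
      !(signal_orientation_right %in% grid))
    stop("signal orientations must lie on the orientation grid")
  if (abs(((signal_orientation_left - signal_orientation_right) %% 180)) != 90)
    stop("left and right signal orientations must differ by 90 degrees")
  structure(list(
    n_orientations = as.integer(n_orientations),
    orientation_spacing = orientation_spacing,
    frame_ms = frame_ms,
    cp_frames = as.integer(cp_frames),
    post_cp_ms = post_cp_ms,
    zcp_min_s = zcp_min_s, zcp_mean_s = zcp_mean_s, zcp_max_s = zcp_max_s,
    signal_orientation_left = signal_orientation_left,
    signal_orientation_right = signal_orientation_right,
    n_seeds = as.integer(n_seeds),
    catch_fraction = catch_fraction,
    grid = grid
  ), class = "stimulus_params")
}

#' Rate of the bounded-exponential ZCP duration distribution
#'
#' The printed duration statistics (min 0.01 s, mean 2.17 s, max 5 s) describe
#' the distribution the subject experiences, i.e. the exponential *truncated*
#' to its bounds. The underlying exponential rate is therefore calibrated by
#' root-finding so that the truncated mean equals `zcp_mean_s`; using the
#' naive rate 1/2.17 would give a truncated mean of about 1.62 s.
#'
#' @param params a [stimulus_params()] object.
#' @return The calibrated rate (1/s).
#' @export
zcp_rate <- function(params = stimulus_params()) {
  a <- params$zcp_min_s; b <- params$zcp_max_s; target <- params$zcp_mean_s
  stopifnot(target > a, target < (a + b) / 2)  # solvable range
  trunc_mean <- function(l) {
    (a * exp(-l * a) - b * exp(-l * b) + (exp(-l * a) - exp(-l * b)) / l) /
      (exp(-l * a) - exp(-l * b))
  }
  uniroot(function(l) trunc_mean(l) - target, c(1e-6, 50), tol = 1e-12)$root
}

#' Sample zero-coherence-period durations
#'
#' Draws from the exponential distribution truncated to
#' `[zcp_min_s, zcp_max_s]` via the inverse CDF, with the rate calibrated by
#' [zcp_rate()] so the sample mean converges to `zcp_mean_s` (2.17 s).
#'
#' @param n number of draws.
#' @param params a [stimulus_params()] object.
#' @return Durations in seconds, all within the bounds.
#' @export
sample_zcp_duration <- function(n, params = stimulus_params()) {
  l <- zcp_rate(params)
  a <- params$zcp_min_s; b <- params$zcp_max_s
  u <- runif(n)
  d <- -log(exp(-l * a) - u * (exp(-l * a) - exp(-l * b))) / l
  clamp(d, a, b)  # guard against round-off at the edges
}

#' Generate a pseudo-random orientation sequence
#'
#' Background (zero-coherence) orientation stream for one stimulus. The
#' stream concatenates independent uniform permutations of the 36-orientation
#' grid, so each orientation is shown once before any repetition, and any
#' 30-frame window contains a given orientation at most twice. The stream is
#' a deterministic function of `(session_seed, seed_id, side)` and is
#' prefix-stable: the first `k` frames are identical for any requested length
#' `n_frames >= k`.
#'
#' @param seed_id integer in `0:(n_seeds - 1)`, one of the session's
#'   repeatable stimulus seeds.
#' @param n_frames number of 10 ms frames to generate.
#' @param params a [stimulus_params()] object.
#' @param side `"left"` or `"right"`; the two sides produce different streams
#'   from the same seed_id.
#' @param session_seed integer identifying the session's stimulus RNG stream.
#' @return An object of class `orientation_sequence` with fields `frames`
#'   (orientations in degrees), `codes` (grid indices 0-35), `seed_id`,
#'   `side`, `signal_mask` (all `FALSE` until a CP is embedded),
#'   `cp_start_frame` (`NA`), and `zcp_frames`.
#' @export
generate_orientation_sequence <- function(seed_id, n_frames,
                                          params = stimulus_params(),
                                          side = c("left", "right"),
                                          session_seed = 0L) {
  side <- match.arg(side)
  if (length(seed_id) != 1L || is.na(seed_id) ||
      seed_id < 0L || seed_id >= params$n_seeds)
    stop("unknown seed_id: must be in 0..", params$n_seeds - 1L)
  stopifnot(n_frames >= 1)
  n_blocks <- ceiling(n_frames / params$n_orientations)
  codes <- with_seed(
    derive_seed(session_seed, 101L + seed_id, (side == "right") * 7L),
    unlist(lapply(seq_len(n_blocks),
                  function(i) sample.int(params$n_orientations) - 1L))
  )[seq_len(n_frames)]
  structure(list(
    codes = codes,
    frames = codes * params$orientation_spacing,
    seed_id = as.integer(seed_id),
    side = side,
    signal_mask = rep(FALSE, n_frames),
    cp_start_frame = NA_integer_,
    zcp_frames = as.integer(n_frames),
    params = params
  ), class = "orientation_sequence")
}

#' Embed a coherent period into an orientation sequence
#'
#' Replaces `coherence` uniformly chosen frames of the 30-frame CP starting
#' at `cp_start_frame` (0-based) with the side's signal orientation and flags
#' them in `signal_mask`. Remaining CP frames continue the background stream
#' but are resampled uniformly from the other 35 orientations if they would
#' show the signal orientation by chance, so that the designed signal count
#' equals `coherence` exactly. Frames after the CP (the 200 ms response tail)
#' are untouched background. Signal frames are not constrained to be
#' contiguous. Consumes the caller's RNG stream.
#'
#' @param seq an `orientation_sequence` long enough to cover
#'   `cp_start_frame + cp_frames` frames.
#' @param coherence number of designed signal frames, `0..cp_frames`.
#' @param cp_start_frame 0-based frame index at which the CP starts (the ZCP
#'   therefore covers frames `0..cp_start_frame - 1`).
#' @return The modified `orientation_sequence` with `cp_start_frame`,
#'   `zcp_frames`, and `signal_mask` set.
#' @export
embed_coherent_period <- function(seq, coherence, cp_start_frame) {
  params <- seq$params
  if (coherence < 0 || coherence > params$cp_frames)
    stop("coherence out of range 0..", params$cp_frames)
  n <- length(seq$codes)
  cp_idx <- cp_start_frame + seq_len(params$cp_frames)  # 1-based indices
  if (max(cp_idx) > n) stop("sequence too short for CP at frame ", cp_start_frame)
  sig_deg <- if (seq$side == "left") params$signal_orientation_left
             else params$signal_orientation_right
  sig_code <- as.integer(sig_deg / params$orientation_spacing)
  sig_pos <- if (coherence > 0) sample(cp_idx, coherence) else integer(0)
  bg_pos <- setdiff(cp_idx, sig_pos)
  hit <- bg_pos[seq$codes[bg_pos] == sig_code]
  if (length(hit)) {
    other <- setdiff(seq_len(params$n_orientations) - 1L, sig_code)
    seq$codes[hit] <- sample(other, length(hit), replace = TRUE)
  }
  seq$codes[sig_pos] <- sig_code
  seq$frames <- seq$codes * params$orientation_spacing
  seq$signal_mask <- rep(FALSE, n)
  seq$signal_mask[sig_pos] <- TRUE
  seq$cp_start_frame <- as.integer(cp_start_frame)
  seq$zcp_frames <- as.integer(cp_start_frame)
  seq
}

#' Build a session's trial schedule
#'
#' Lays out attention blocks and per-trial stimulus parameters. Blocks are
#' randomized in sets of three so every attention condition occurs once
#' before any repeats. Each block carries a pool of `trials_per_block` trial
#' specifications; during simulation a block advances once 60 hit-or-miss
#' trials have been counted (false alarms and catch trials do not count), so
#' the pool is oversized and the block-advance rule is exposed via the
#' `counted_per_block` attribute rather than a fixed trial count. Within each
#' condition 10% of trials are catch trials (independent Bernoulli draws);
#' non-catch AB trials split the change side 50/50; AB coherences are the
#' base set plus one frame; the stimulus seed is uniform over the session's
#' five seeds.
#'
#' @param config list with elements `base_coherences` (five signal-frame
#'   counts), `rf_side` (`"left"` or `"right"`, the stimulus over the
#'   recorded receptive fields), `n_blocks` (multiple of 3), and optionally
#'   `trials_per_block` (pool size, default 110) and `stim_params`.
#' @return A `data.frame` (class `session_schedule`) with one row per
#'   scheduled trial: `trial`, `block`, `condition`, `seed_id`, `zcp_s`,
#'   `zcp_frames`, `coherence`, `change_side`, `is_catch`. Attributes carry
#'   `counted_per_block` and the stimulus parameters.
#' @export
build_session_schedule <- function(config) {
  params <- config$stim_params %||% stimulus_params()
  base <- config$base_coherences
  if (length(base) < 5) stop("need at least 5 base coherences")
  rf <- match.arg(config$rf_side, c("left", "right"))
  away <- if (rf == "left") "right" else "left"
  n_blocks <- config$n_blocks
  tpb <- config$trials_per_block %||% 110L
  conds <- unlist(lapply(seq_len(ceiling(n_blocks / 3)),
                         function(i) sample(c("AI", "AB", "AO"))))[seq_len(n_blocks)]
  rows <- lapply(seq_len(n_blocks), function(b) {
    cond <- conds[b]
    is_catch <- runif(tpb) < params$catch_fraction
    coh <- sample(base, tpb, replace = TRUE)
    if (cond == "AB") coh <- coh + 1L
    side <- switch(cond,
      AI = rep(rf, tpb),
      AO = rep(away, tpb),
      AB = sample(c("left", "right"), tpb, replace = TRUE))
    side[is_catch] <- "none"
    coh[is_catch] <- 0L
    zcp <- sample_zcp_duration(tpb, params)
    data.frame(block = b, condition = cond,
               seed_id = sample.int(params$n_seeds, tpb, replace = TRUE) - 1L,
               zcp_s = zcp,
               zcp_frames = pmax(1L, as.integer(round(zcp * 1000 / params$frame_ms))),
               coherence = as.integer(coh), change_side = side,
               is_catch = is_catch, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(trial = seq_len(nrow(out)), out)
  attr(out, "counted_per_block") <- 60L
  attr(out, "stim_params") <- params
  attr(out, "rf_side") <- rf
  class(out) <- c("session_schedule", "data.frame")
  out
}
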