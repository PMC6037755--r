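#' Classify a trial outcome from the saccade record
#'
#' Outcomes: *hit* — saccade to the changed stimulus within the response
#' window (100 ms after CP onset to 200 ms after CP end); *miss* — change
#' trial with no valid saccade; *correct rejection* — fixation maintained
#' on a catch trial; *false alarm* — any saccade before the response window
#' opens (including during the 100 ms lockout) or, on change trials, a
#' saccade to the unchanged stimulus within the window.
#'
#' @param trial list or one-row data frame with `zcp_s`, `change_side`,
#'   `is_catch`.
#' @param saccade_side `"left"`, `"right"` or `"none"`.
#' @param saccade_ms saccade time relative to stimulus onset (`NA` if none).
#' @param stim a [stimulus_params()] object.
#' @param lockout_ms response lockout after CP onset.
#' @return One of `"hit"`, `"miss"`, `"correct_rejection"`, `"false_alarm"`.
#' @export
classify_outcome <- function(trial, saccade_side, saccade_ms,
                             stim = stimulus_params(), lockout_ms = 100) {
  if (trial$is_catch)
    return(if (saccade_side == "none") "correct_rejection" else "false_alarm")
  if (saccade_side == "none") return("miss")
  cp_on <- trial$zcp_s * 1000
  win_open <- cp_on + lockout_ms
  win_close <- cp_on + stim$cp_frames * stim$frame_ms + stim$post_cp_ms
  if (saccade_ms < win_open) return("false_alarm")
  if (saccade_ms > win_close) return("miss")  # too late to count
  if (saccade_side == trial$change_side) "hit" else "false_alarm"
}

#' Fit psychometric functions and extract 50% thresholds
#'
#' Maximum-likelihood logistic fit of detection (hit vs miss) against
#' coherence per attention condition, with the 50% performance threshold
#' `-b0/b1` and a bootstrap percentile confidence interval (trials
#' resampled with replacement). Fits with complete separation or a
#' non-positive slope are flagged degenerate.
#'
#' @param trials `data.frame` with `condition`, `coherence`, `outcome`
#'   (only `"hit"`/`"miss"` rows are used).
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param conf confidence level.
#' @return `data.frame(condition, threshold_50, slope, ci_lo, ci_hi, n,
#'   degenerate)` plus a `fraction_detected` attribute with the
#'   per-coherence detected fractions.
#' @export
fit_psychometric <- function(trials, n_boot = 2000L, conf = 0.95) {
  hm <- trials[trials$outcome %in% c("hit", "miss"), , drop = FALSE]
  hm$detected <- as.integer(hm$outcome == "hit")
  fit1 <- function(d) {
    agg <- aggregate(detected ~ coherence, d, function(x) c(k = sum(x), n = length(x)))
    k <- agg$detected[, "k"]; n <- agg$detected[, "n"]
    if (length(unique(agg$coherence)) < 2L) return(c(NA, NA))
    if (all(k == 0) || all(k == n)) return(c(NA, NA))
    fit <- suppressWarnings(
      glm(cbind(k, n - k) ~ agg$coherence, family = binomial()))
    b <- coef(fit)
    if (!is.finite(b[2L]) || b[2L] <= 0) return(c(NA, NA))
    c(-b[1L] / b[2L], b[2L])
  }
  res <- list(); fracs <- list()
  for (cc in unique(hm$condition)) {
    d <- hm[hm$condition == cc, , drop = FALSE]
    est <- fit1(d)
    boot <- rep(NA_real_, n_boot)
    if (is.finite(est[1L]) && n_boot > 0) {
      for (b in seq_len(n_boot))
        boot[b] <- fit1(d[sample.int(nrow(d), replace = TRUE), ])[1L]
      ci <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    } else ci <- c(NA_real_, NA_real_)
    res[[cc]] <- data.frame(
      condition = cc, threshold_50 = est[1L], slope = est[2L],
      ci_lo = ci[1L], ci_hi = ci[2L], n = nrow(d),
      degenerate = !is.finite(est[1L]))
    fr <- aggregate(detected ~ coherence, d, mean)
    fr$condition <- cc
    fracs[[cc]] <- fr
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "fraction_detected") <- do.call(rbind, fracs)
  out
}

#' Per-condition behavioral summary of a session
#'
#' Detection percentage `hits / (hits + misses)`, false-alarm rate over all
#' valid trials `FA / (hits + misses + CR + FA)`, and the median and median
#' absolute deviation of reaction times on hit trials.
#'
#' @param trials `data.frame` with `condition`, `outcome`, and `rt_ms`
#'   (reaction time relative to CP onset; `NA` on non-hits).
#' @return `data.frame(condition, n, detected_pct, fa_pct, median_rt_ms,
#'   mad_rt_ms)`; conditions with no trials are omitted with a warning.
#' @export
session_behavior_summary <- function(trials) {
  conds <- c("AI", "AB", "AO")
  present <- intersect(conds, unique(trials$condition))
  if (length(present) < length(conds))
    warning("conditions with no trials omitted from behavior summary")
  out <- lapply(present, function(cc) {
    d <- trials[trials$condition == cc, , drop = FALSE]
    n_out <- table(factor(d$outcome,
      levels = c("hit", "miss", "correct_rejection", "false_alarm")))
    hm <- n_out[["hit"]] + n_out[["miss"]]
    rt <- d$rt_ms[d$outcome == "hit"]
    data.frame(
      condition = cc, n = nrow(d),
      detected_pct = if (hm > 0) 100 * n_out[["hit"]] / hm else NA_real_,
      fa_pct = 100 * n_out[["false_alarm"]] / sum(n_out),
      median_rt_ms = if (length(rt)) median(rt) else NA_real_,
      mad_rt_ms = if (length(rt)) median(abs(rt - median(rt))) else NA_real_)
  })
  do.call(rbind, out)
}
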