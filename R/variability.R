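#' Block-wise z-scoring of spike counts
#'
#' Z-scores spike counts within cells of identical stimulus and slow-rate
#' context to control for slow firing-rate fluctuations across a session.
#' The grouping cell is `(unit, condition, seed, block)`; cells with fewer
#' than `min_trials` trials fall back to `(unit, condition, seed)`
#' statistics computed session-wide. Cells (after fallback) with zero
#' standard deviation or still fewer than `min_trials` trials are dropped.
#'
#' @param counts `data.frame` with columns `unit`, `trial`, `condition`,
#'   `seed_id`, `block`, `count`.
#' @param min_trials minimum trials per cell (default 3).
#' @return The input rows that survive, with a `z` column appended.
#' @export
blockwise_zscore <- function(counts, min_trials = 3L) {
  dt <- data.table::as.data.table(counts)
  dt[, `:=`(cell_n = .N, cell_m = mean(count), cell_s = sd(count)),
     by = .(unit, condition, seed_id, block)]
  dt[, `:=`(fb_n = .N, fb_m = mean(count), fb_s = sd(count)),
     by = .(unit, condition, seed_id)]
  fallback <- dt$cell_n < min_trials
  dt[, n_use := ifelse(fallback, fb_n, cell_n)]
  dt[, m_use := ifelse(fallback, fb_m, cell_m)]
  dt[, s_use := ifelse(fallback, fb_s, cell_s)]
  dt <- dt[n_use >= min_trials & s_use > 0]
  if (!nrow(dt)) stop("all grouping cells degenerate")
  dt[, z := (count - m_use) / s_use]
  out <- as.data.frame(dt[, .(unit, trial, condition, seed_id, block, count, z)])
  out
}

#' Spike-count correlation of a unit pair
#'
#' Pearson correlation of two units' z-scored counts over aligned trials
#' (identical repetitions pooled over seeds and blocks within a condition).
#'
#' @param zA,zB aligned z-score vectors.
#' @return Correlation coefficient; `NA` with a warning if fewer than 3
#'   paired observations.
#' @export
spike_count_correlation <- function(zA, zB) {
  ok <- is.finite(zA) & is.finite(zB)
  if (sum(ok) < 3L) {
    warning("fewer than 3 paired observations: r_sc undefined")
    return(NA_real_)
  }
  cor(zA[ok], zB[ok])
}

#' All pairwise spike-count correlations by condition
#'
#' Convenience wrapper: pivots a block-wise z-score table to a trial x unit
#' matrix per condition and computes all pairwise correlations on
#' pairwise-complete trials.
#'
#' @param z output of [blockwise_zscore()].
#' @param min_trials minimum paired trials for a pair to be reported.
#' @return `data.frame(condition, unit_a, unit_b, r_sc, n)`.
#' @export
pairwise_rsc <- function(z, min_trials = 3L) {
  out <- list()
  for (cc in unique(z$condition)) {
    sub <- z[z$condition == cc, , drop = FALSE]
    units <- sort(unique(sub$unit))
    trials <- sort(unique(sub$trial))
    m <- matrix(NA_real_, length(trials), length(units),
                dimnames = list(NULL, units))
    m[cbind(match(sub$trial, trials), match(sub$unit, units))] <- sub$z
    for (i in seq_along(units)) for (j in seq_len(i - 1L)) {
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      n <- sum(ok)
      r <- if (n >= min_trials) cor(m[ok, i], m[ok, j]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        condition = cc, unit_a = units[j], unit_b = units[i], r_sc = r, n = n)
    }
  }
  do.call(rbind, out)
}

#' Block-wise Fano factor
#'
#' Spike-count variance divided by mean per `(unit, condition, seed,
#' block)` cell (unbiased variance), combined across cells by trial-count
#' weighting. Cells with zero mean or fewer than `min_trials` trials are
#' dropped.
#'
#' @param counts as in [blockwise_zscore()].
#' @param min_trials minimum trials per cell.
#' @return `data.frame(unit, condition, fano, n_trials)`.
#' @export
fano_factor <- function(counts, min_trials = 3L) {
  dt <- data.table::as.data.table(counts)
  cells <- dt[, .(n = .N, m = mean(count), v = var(count)),
              by = .(unit, condition, seed_id, block)]
  cells <- cells[n >= min_trials & m > 0]
  if (!nrow(cells)) stop("all Fano cells degenerate")
  out <- cells[, .(fano = sum(n * v / m) / sum(n), n_trials = sum(n)),
               by = .(unit, condition)]
  as.data.frame(out)
}

#' Correlation contrast versus stimulus eccentricity
#'
#' Pearson correlation across sessions between the Attend-Both correlation
#' contrast, `r_AB - (r_AI + r_AO)/2`, and the horizontal eccentricity of
#' the stimuli, with `t = r * sqrt((n-2)/(1-r^2))` and a two-tailed p-value.
#'
#' @param contrast per-session correlation contrasts.
#' @param eccentricity_deg per-session horizontal eccentricities.
#' @return List with `r`, `t`, `df`, `p`, `n`.
#' @export
eccentricity_trend <- function(contrast, eccentricity_deg) {
  ok <- is.finite(contrast) & is.finite(eccentricity_deg)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 sessions")
  if (var(eccentricity_deg[ok]) == 0) stop("constant eccentricities")
  r <- cor(contrast[ok], eccentricity_deg[ok])
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2L, p = 2 * pt(-abs(t), n - 2L), n = n)
}
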