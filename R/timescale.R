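# FFT cross-correlation r(tau) = sum_t a_t * b_{t+tau}, tau = -(T-1)..(T-1)
# a, b: matrices (time x trials); returns summed-over-trials correlation
xcorr_sum <- function(a, b) {
  T <- nrow(a)
  L <- nextn(2L * T - 1L, 2L)
  pad <- function(m) rbind(m, matrix(0, L - T, ncol(m)))
  Fa <- mvfft(pad(a)); Fb <- mvfft(pad(b))
  r <- Re(mvfft(as.matrix(rowSums(Conj(Fa) * Fb)), inverse = TRUE)) / L
  # index tau+1 for tau >= 0; L+tau+1 for tau < 0
  c(r[(L - T + 2L):L], r[1L:T])  # lags -(T-1)..(T-1)
}

#' Shift-corrected cross-correlogram of a unit pair
#'
#' Computes the trial-averaged spike-train cross-correlogram at 1 ms lags
#' over the first `T_ms` of the zero-coherence period, the seed-matched
#' shift predictor (the cross-correlation of the two units' trial-averaged
#' spike density functions, computed separately per stimulus seed because
#' different seeds show different stimuli), and their difference, the
#' corrected correlogram `C_jk(tau)`. The raw correlogram and predictor are
#' also reported normalized by the triangular lag-overlap factor
#' `T - |tau|`, which cancels in the correction. Passing the same unit
#' twice yields the auto-correlogram; its zero-lag bin retains the spike-
#' count term so that the integral identity with the spike-count variance
#' holds.
#'
#' @param spA,spB lists (per trial) of spike times in ms within `[0, T_ms)`.
#' @param seed per-trial stimulus seed ids (same length as the lists).
#' @param T_ms counting window (default 1000).
#' @return Object of class `correlogram`: `lags` (-(T-1)..(T-1) ms),
#'   `corrected` (coincidence counts per trial), `ccg` (triangle-normalized
#'   corrected correlogram), `raw`, `predictor`, `n_trials`.
#' @export
cross_correlogram <- function(spA, spB, seed = rep(0L, length(spA)),
                              T_ms = 1000L) {
  stopifnot(length(spA) == length(spB), length(spA) == length(seed))
  if (sum(lengths(spA)) == 0L || sum(lengths(spB)) == 0L)
    stop("no spikes in one of the trains")
  T <- as.integer(T_ms)
  binm <- function(sp) vapply(sp, function(tt)
    tabulate(floor(tt[tt >= 0 & tt < T]) + 1L, T), numeric(T))
  raw <- numeric(2L * T - 1L); pred <- numeric(2L * T - 1L)
  ntot <- 0L
  for (s in unique(seed)) {
    idx <- which(seed == s)
    A <- binm(spA[idx]); B <- binm(spB[idx])
    ns <- length(idx)
    raw <- raw + xcorr_sum(A, B)
    psa <- rowMeans(A); psb <- rowMeans(B)
    pred <- pred + ns * xcorr_sum(as.matrix(psa), as.matrix(psb))
    ntot <- ntot + ns
  }
  raw <- raw / ntot; pred <- pred / ntot
  lags <- -(T - 1L):(T - 1L)
  tri <- T - abs(lags)
  structure(list(lags = lags, corrected = raw - pred,
                 ccg = (raw - pred) / tri,
                 raw = raw / tri, predictor = pred / tri,
                 n_trials = ntot, T_ms = T),
            class = "correlogram")
}

#' Cumulative correlation coefficient r_CCG
#'
#' Integrates the shift-corrected cross-correlogram over increasing lag
#' windows, `A_jk(tau) = sum_{|t| < tau} C_jk(t)`, and normalizes by the
#' full-window auto-correlogram integrals:
#' `r_CCG(tau) = A_jk(tau) / sqrt(A_jj(T) * A_kk(T))`.
#' The integration uses the unnormalized coincidence counts (the
#' triangle-normalized display correlogram is undone), which is what makes
#' `r_CCG(T)` equal the Pearson correlation of the `T`-window spike counts
#' on the same trials.
#'
#' @param cjk,cjj,ckk `correlogram` objects for the cross- and the two
#'   auto-correlograms (same `T_ms`).
#' @return `data.frame(tau_ms, A_jk, r_ccg)` for `tau` = 1..T ms (the window
#'   `tau` includes lags `|t| <= tau - 1`). If either auto-integral at `T`
#'   is non-positive, `r_ccg` is `NA` with a warning.
#' @export
cumulative_r_ccg <- function(cjk, cjj, ckk) {
  T <- cjk$T_ms
  stopifnot(cjj$T_ms == T, ckk$T_ms == T)
  cum_sym <- function(cg) {
    x <- cg$corrected
    zero <- which(cg$lags == 0L)
    c(x[zero], x[zero] + cumsum(x[zero + seq_len(T - 1L)] +
                                x[zero - seq_len(T - 1L)]))
  }
  Ajk <- cum_sym(cjk)
  Ajj_T <- cum_sym(cjj)[T]
  Akk_T <- cum_sym(ckk)[T]
  denom <- Ajj_T * Akk_T
  if (!is.finite(denom) || denom <= 0) {
    warning("non-positive auto-correlogram integral: r_CCG undefined")
    r <- rep(NA_real_, T)
  } else r <- Ajk / sqrt(denom)
  data.frame(tau_ms = seq_len(T), A_jk = Ajk, r_ccg = r)
}

#' Session-mean r_CCG curves by attention condition
#'
#' Computes `r_CCG(tau)` for every unit pair in each condition and averages
#' the curves across pairs (pairs within a session first; session curves
#' can then be averaged by the caller).
#'
#' @param spikes `data.frame(unit, trial, time_ms)` restricted to the
#'   zero-coherence period.
#' @param trials `data.frame(trial, condition, seed_id)` of the trials to
#'   use (typically correct trials with sufficient ZCP length).
#' @param units unit ids to include.
#' @param T_ms counting window.
#' @param tau_subset optional lag subset (ms) at which to report the mean
#'   curve (defaults to all 1..T).
#' @return `data.frame(condition, tau_ms, r_ccg, n_pairs)`.
#' @export
session_rccg <- function(spikes, trials, units = sort(unique(spikes$unit)),
                         T_ms = 1000L, tau_subset = NULL) {
  T <- as.integer(T_ms)
  L <- nextn(2L * T - 1L, 2L)
  tau <- tau_subset %||% seq_len(T)
  out <- list()
  for (cc in unique(trials$condition)) {
    tr <- trials[trials$condition == cc, , drop = FALSE]
    # per-seed FFTs of every unit's binned trials, plus PSTH spectra
    spec <- list(); nseed <- integer(0)
    for (s in sort(unique(tr$seed_id))) {
      ids <- tr$trial[tr$seed_id == s]
      if (!length(ids)) next
      A <- lapply(units, function(u) {
        m <- matrix(0, T, length(ids))
        sub <- spikes[spikes$unit == u & spikes$trial %in% ids, , drop = FALSE]
        if (nrow(sub)) {
          ti <- match(sub$trial, ids)
          b <- floor(sub$time_ms) + 1L
          ok <- b >= 1L & b <= T
          for (r in which(ok)) m[b[r], ti[r]] <- m[b[r], ti[r]] + 1
        }
        m
      })
      Fs <- lapply(A, function(m) mvfft(rbind(m, matrix(0, L - T, ncol(m)))))
      Ps <- lapply(A, function(m) fft(c(rowMeans(m), numeric(L - T))))
      spec[[length(spec) + 1L]] <- list(F = Fs, P = Ps, n = length(ids))
      nseed <- c(nseed, length(ids))
    }
    ntot <- sum(nseed)
    if (ntot < 3L) next
    nu <- length(units)
    corr_counts <- function(j, k) {
      acc <- numeric(L)
      for (sp in spec) {
        acc <- acc + rowSums(Conj(sp$F[[j]]) * sp$F[[k]]) -
          sp$n * Conj(sp$P[[j]]) * sp$P[[k]]
      }
      r <- Re(fft(acc, inverse = TRUE)) / L / ntot
      c(r[(L - T + 2L):L], r[1L:T])  # lags -(T-1)..(T-1)
    }
    cum_at <- function(x) {
      zero <- T
      a <- c(x[zero], x[zero] + cumsum(x[zero + seq_len(T - 1L)] +
                                       x[zero - seq_len(T - 1L)]))
      a
    }
    autoT <- vapply(seq_len(nu), function(j) cum_at(corr_counts(j, j))[T],
                    numeric(1L))
    curves <- matrix(0, length(tau), 0L)
    for (j in seq_len(nu)) for (k in seq_len(nu)) {
      if (k <= j) next
      if (autoT[j] <= 0 || autoT[k] <= 0) next
      a <- cum_at(corr_counts(j, k))
      curves <- cbind(curves, a[tau] / sqrt(autoT[j] * autoT[k]))
    }
    if (!ncol(curves)) next
    out[[length(out) + 1L]] <- data.frame(
      condition = cc, tau_ms = tau, r_ccg = rowMeans(curves),
      n_pairs = ncol(curves))
  }
  do.call(rbind, out)
}
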