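#' Detect microsaccades from a 2-D gaze trace
#'
#' Velocity-criterion detector: samples whose displacement over the
#' preceding `window_ms` exceeds `threshold_deg` (0.1 deg in 10 ms, i.e.
#' 10 deg/s) are supra-threshold; maximal runs of supra-threshold samples
#' (with gaps up to `merge_gap_ms` merged) form one event. Event amplitude
#' is the net displacement from just before onset to offset and the
#' direction its `atan2` angle mapped into `[0, 360)`, binned into eight
#' 45-degree sectors centered on the cardinal and oblique axes. The
#' detector is invariant to global gaze-offset translation. Events spanning
#' gaps in the timestamps are rejected.
#'
#' @param t_ms,x,y gaze timestamps (ms) and position (deg).
#' @param threshold_deg displacement criterion over the velocity window.
#' @param window_ms velocity window (default 10 ms).
#' @param merge_gap_ms sub-threshold gaps up to this length are merged.
#' @return `data.frame(onset_ms, offset_ms, amplitude_deg, direction_deg,
#'   direction_bin)` with `direction_bin` in `0..7` (bin 0 = `[-22.5,
#'   22.5)` degrees).
#' @export
detect_microsaccades <- function(t_ms, x, y, threshold_deg = 0.1,
                                 window_ms = 10, merge_gap_ms = 5) {
  n <- length(t_ms)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 3L) return(empty_ms_events())
  dt <- median(diff(t_ms))
  k <- max(1L, as.integer(round(window_ms / dt)))
  idx <- (k + 1L):n
  disp <- sqrt((x[idx] - x[idx - k])^2 + (y[idx] - y[idx - k])^2)
  gap <- c(FALSE, diff(t_ms) > 2.5 * dt)
  supra <- disp > threshold_deg
  if (!any(supra)) return(empty_ms_events())
  sup_idx <- idx[supra]
  brk <- which(diff(sup_idx) > max(1, merge_gap_ms / dt))
  starts <- sup_idx[c(1L, brk + 1L)]
  ends <- sup_idx[c(brk, length(sup_idx))]
  rows <- lapply(seq_along(starts), function(e) {
    i0 <- max(1L, starts[e] - k)   # position just before the movement began
    i1 <- ends[e]
    if (any(gap[i0:i1])) return(NULL)  # event spans a recording gap
    dx <- x[i1] - x[i0]; dy <- y[i1] - y[i0]
    dir <- (atan2(dy, dx) * 180 / pi) %% 360
    data.frame(onset_ms = t_ms[starts[e]] - window_ms, offset_ms = t_ms[i1],
               amplitude_deg = sqrt(dx^2 + dy^2), direction_deg = dir,
               direction_bin = floor(((dir + 22.5) %% 360) / 45))
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty_ms_events())
  do.call(rbind, rows)
}

empty_ms_events <- function() {
  data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
             amplitude_deg = numeric(0), direction_deg = numeric(0),
             direction_bin = integer(0))
}

#' Microsaccade statistics by attention condition
#'
#' Event counts per condition normalized first by the analyzed
#' zero-coherence time in that condition (a rate) and then by the session
#' mean rate, plus the eight-bin direction distribution as proportions of
#' the session's event total.
#'
#' @param events `data.frame` with `condition` and `direction_bin`.
#' @param analyzed_s named vector of analyzed ZCP time (s) per condition.
#' @return List with `normalized_count` (per condition) and
#'   `direction_distribution` (condition x 8 matrix of proportions). With
#'   zero events the distribution is flagged undefined (`NA`) with a
#'   warning.
#' @export
microsaccade_stats <- function(events, analyzed_s) {
  conds <- names(analyzed_s)
  if (!nrow(events)) {
    warning("no events: direction distribution undefined")
    return(list(normalized_count = setNames(rep(NA_real_, length(conds)), conds),
                direction_distribution = matrix(NA_real_, length(conds), 8L,
                                                dimnames = list(conds, 0:7))))
  }
  rate <- vapply(conds, function(cc)
    sum(events$condition == cc) / analyzed_s[[cc]], numeric(1L))
  dist <- t(vapply(conds, function(cc)
    tabulate(events$direction_bin[events$condition == cc] + 1L, 8L),
    numeric(8L)))
  dimnames(dist) <- list(conds, 0:7)
  list(normalized_count = rate / mean(rate),
       direction_distribution = dist / nrow(events))
}

#' @importFrom stats setNames
NULL
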