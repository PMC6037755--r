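#' Current source density from laminar LFPs
#'
#' CSD as the negative second spatial difference of the trial-averaged,
#' stimulus-locked LFP across equally spaced channels,
#' `CSD_j = -(V_{j-1} - 2 V_j + V_{j+1}) / h^2`, with boundary channels
#' handled by edge replication, followed by Gaussian smoothing over depth
#' and time. Sinks are negative (physics sign convention). The
#' earliest-sink channel is the channel whose CSD first reaches sink
#' polarity at a substantial fraction of the global sink extremum after
#' stimulus onset, the default heuristic for locating the layer 4-5
#' transition.
#'
#' @param lfp `channels x time` matrix of trial-averaged LFP.
#' @param spacing_um channel spacing (default 60).
#' @param smooth_sd_ch,smooth_sd_t Gaussian smoothing SDs in channels and
#'   time samples.
#' @param onset_sample first post-onset column to search for sinks.
#' @param sink_fraction fraction of the global sink extremum a channel must
#'   reach to count as a sink.
#' @return Object of class `csd_profile`: `csd` (channels x time,
#'   V/um^2 up to a conductivity constant), `earliest_sink_channel`,
#'   `spacing_um`.
#' @export
compute_csd <- function(lfp, spacing_um = 60, smooth_sd_ch = 0.8,
                        smooth_sd_t = 0, onset_sample = 1L,
                        sink_fraction = 0.5) {
  nc <- nrow(lfp)
  if (nc < 3L) stop("need at least 3 channels")
  vp <- rbind(lfp[1L, ], lfp, lfp[nc, ])  # edge replication
  csd <- -(vp[1:nc, ] - 2 * vp[2:(nc + 1L), ] + vp[3:(nc + 2L), ]) / spacing_um^2
  if (smooth_sd_ch > 0) {
    k <- gaussian_kernel(smooth_sd_ch)
    csd <- apply(csd, 2L, smooth_replicate, kernel = k)
  }
  if (smooth_sd_t > 0) {
    k <- gaussian_kernel(smooth_sd_t)
    csd <- t(apply(csd, 1L, smooth_replicate, kernel = k))
  }
  post <- csd[, onset_sample:ncol(csd), drop = FALSE]
  gmin <- min(post)
  sink_ch <- NA_integer_
  if (gmin < 0) {
    level <- sink_fraction * gmin
    first_t <- apply(post, 1L, function(v) {
      w <- which(v <= level)
      if (length(w)) w[1L] else Inf
    })
    sink_ch <- which.min(first_t)
  }
  structure(list(csd = csd, earliest_sink_channel = sink_ch,
                 spacing_um = spacing_um),
            class = "csd_profile")
}

#' Assign units to laminar groups by depth
#'
#' Depths are relative to the first layer-5 channel (the zero-point;
#' positive = deeper). The granular group (G) is the 400 um band just
#' superficial to the zero-point (`-400 <= depth < 0`), supragranular (S)
#' everything above it (`depth < -400`), infragranular (I) everything at or
#' below the zero-point. Depths off the channel grid are snapped to the
#' nearest channel with a warning. A robustness mode re-labels with the
#' S-G boundary shifted over a span of channels and reports the fraction
#' of units whose label never changes.
#'
#' @param depth_um unit depths relative to the first L5 channel.
#' @param spacing_um channel spacing.
#' @param granular_band_um thickness of the granular band (default 400).
#' @param boundary_shifts_um shifts of the S-G boundary to probe (default
#'   -120..120 um in channel steps, a span of nearly 200 um around each
#'   side of the nominal boundary).
#' @return `data.frame(depth_um, label)` with `label` in `c("S","G","I")`,
#'   plus attributes `stability` (fraction of units stable under boundary
#'   shifts) and `labels_by_shift`.
#' @export
assign_layers <- function(depth_um, spacing_um = 60, granular_band_um = 400,
                          boundary_shifts_um = seq(-120, 120, by = 60)) {
  snapped <- round(depth_um / spacing_um) * spacing_um
  if (any(snapped != depth_um))
    warning("depths off the channel grid snapped to nearest channel")
  # labels use the stated depths so the -400 um band edge stays inclusive
  lab <- function(shift) {
    sg <- -granular_band_um + shift  # S-G boundary depth
    ifelse(depth_um >= 0, "I", ifelse(depth_um >= sg, "G", "S"))
  }
  labels <- lab(0)
  byshift <- vapply(boundary_shifts_um, lab, character(length(snapped)))
  stable <- apply(as.matrix(byshift), 1L, function(r) length(unique(r)) == 1L)
  out <- data.frame(depth_um = depth_um, channel_depth_um = snapped,
                    label = labels, stringsAsFactors = FALSE)
  attr(out, "stability") <- mean(stable)
  attr(out, "labels_by_shift") <- byshift
  out
}
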