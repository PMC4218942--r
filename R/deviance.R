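# Epoching, condition ERPs, the Deviant-minus-Standard auditory deviance
# response, cluster back-projection with percent-variance-accounted-for
# (pvaf) accounting, and MMN/P3a/RON peak scoring.

#' Default peak search windows (ms) and nominal polarities
#' @export
peak_windows <- function() {
  list(MMN = list(window = c(140, 240), polarity = -1),
       P3a = list(window = c(220, 340), polarity = +1),
       RON = list(window = c(310, 460), polarity = -1))
}

#' Epoch a signal around events and average one condition
#'
#' Epochs span -100..500 ms (half-open in samples). The baseline mean
#' (-100..0 ms) is subtracted AFTER averaging — and, for IC activations,
#' after decomposition, never before it. Events whose onset sample is not
#' retained, or whose epoch leaves the data, are excluded.
#'
#' @param x channels x samples matrix (or a vector for one IC activation).
#' @param fs sampling rate (Hz). @param events an [event_sequence()].
#' @param condition `"standard"` or `"deviant"`.
#' @param retained_mask optional per-sample logical mask.
#' @param tmin_ms,tmax_ms epoch limits (ms relative to onset).
#' @return an `erp`: list with `time_ms`, `waveform` (channels x time),
#'   `n_trials`, `condition`.
#' @export
epoch_and_average <- function(x, fs, events, condition,
                              retained_mask = NULL,
                              tmin_ms = -100, tmax_ms = 500) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n <- ncol(x)
  pre <- round(-tmin_ms / 1000 * fs)
  post <- round(tmax_ms / 1000 * fs)
  sel <- events$codes == condition
  on <- events$onsets[sel]
  if (!is.null(retained_mask)) on <- on[retained_mask[on + 1]]
  on <- on[on - pre >= 0 & on + post <= n]
  if (!length(on))
    abort_validation("no retained '", condition, "' trials to average")
  acc <- matrix(0, nrow(x), pre + post + 1)
  for (o in on) acc <- acc + x[, (o - pre + 1):(o + post + 1), drop = FALSE]
  avg <- acc / length(on)
  time_ms <- seq(-pre, post) / fs * 1000
  bl <- rowMeans(avg[, time_ms <= 0, drop = FALSE])
  avg <- avg - bl
  structure(list(time_ms = time_ms, waveform = avg, n_trials = length(on),
                 condition = condition), class = "erp")
}

#' Deviant-minus-Standard difference waveform
#' @param erp_dev,erp_std `erp` objects on a common time base.
#' @return an `erp` with `condition = "deviance"`.
#' @export
deviance_response <- function(erp_dev, erp_std) {
  if (length(erp_dev$time_ms) != length(erp_std$time_ms) ||
      any(abs(erp_dev$time_ms - erp_std$time_ms) > 1e-9))
    abort_validation("condition ERPs are on different time bases")
  structure(list(time_ms = erp_dev$time_ms,
                 waveform = erp_dev$waveform - erp_std$waveform,
                 n_trials = c(deviant = erp_dev$n_trials, standard = erp_std$n_trials),
                 condition = "deviance"), class = "erp")
}

#' Back-project a set of ICs to channel space
#'
#' Channel waveforms are the sum over members of scalp map times source ERP.
#' Members are polarity-aligned first (any member whose map correlates
#' negatively with the cluster-mean map has its map and waveform flipped,
#' which leaves each member's back-projection unchanged). The summary trace
#' is the RMS across channels, signed by the sign of the back-projected
#' waveform at the channel of maximal absolute cluster-map projection.
#'
#' @param maps channels x members matrix of scalp maps.
#' @param waveforms members x time matrix of source ERPs (scalp-projected
#'   units as produced on IC activations).
#' @return list with `channel_waveforms` (channels x time), `trace` (signed
#'   RMS over channels), `mean_map`.
#' @export
backproject <- function(maps, waveforms) {
  maps <- as.matrix(maps); waveforms <- as.matrix(waveforms)
  if (ncol(maps) == 0 || nrow(waveforms) == 0) {
    return(list(channel_waveforms = matrix(0, nrow(maps), ncol(waveforms)),
                trace = numeric(ncol(waveforms)), mean_map = rep(0, nrow(maps))))
  }
  ref <- maps[, 1]
  for (j in seq_len(ncol(maps))) {
    if (sum(maps[, j] * ref) < 0) {
      maps[, j] <- -maps[, j]; waveforms[j, ] <- -waveforms[j, ]
    }
  }
  mean_map <- rowMeans(maps)
  chan <- maps %*% waveforms
  cstar <- which.max(abs(mean_map))
  trace <- sqrt(colMeans(chan^2)) * sign(chan[cstar, ])
  list(channel_waveforms = chan, trace = as.numeric(trace), mean_map = mean_map)
}

#' Percent variance accounted for by a component waveform set
#'
#' `pvaf = 100 * (1 - var(total - component) / var(total))`, variance pooled
#' over all channels and the window's samples. May be negative for
#' components anticorrelated with (or orthogonal to) the total.
#'
#' @param component,total channels x time matrices on the same basis.
#' @param time_ms optional time base; with `window`, restricts the samples.
#' @param window `c(lo, hi)` ms (default 0..500 when `time_ms` given).
#' @return pvaf in percent.
#' @export
pvaf <- function(component, total, time_ms = NULL, window = c(0, 500)) {
  component <- as.matrix(component); total <- as.matrix(total)
  if (!all(dim(component) == dim(total)))
    abort_validation("component and total must have identical dimensions")
  if (!is.null(time_ms)) {
    sel <- time_ms >= window[1] & time_ms <= window[2]
    component <- component[, sel, drop = FALSE]
    total <- total[, sel, drop = FALSE]
  }
  vt <- stats::var(as.numeric(total))
  if (vt == 0) abort_validation("total waveform has zero variance; pvaf undefined")
  100 * (1 - stats::var(as.numeric(total - component)) / vt)
}

#' Score MMN / P3a / RON peaks on a deviance waveform
#'
#' For each peak the latency is the time of the window extremum of the
#' nominal polarity (earliest sample on ties); the amplitude is the mean
#' voltage over latency +/- 10 ms; an edge flag marks extrema sitting on a
#' window boundary. `polarity = "free"` searches the absolute extremum
#' instead (medial-source projections can invert).
#'
#' @param waveform numeric vector. @param time_ms its time base (ms).
#' @param windows list as [peak_windows()].
#' @param polarity `"nominal"` or `"free"`.
#' @return data.frame: peak, latency_ms, amplitude, edge_flag.
#' @export
score_peaks <- function(waveform, time_ms, windows = peak_windows(),
                        polarity = c("nominal", "free")) {
  polarity <- match.arg(polarity)
  rows <- lapply(names(windows), function(nm) {
    wdef <- windows[[nm]]
    sel <- which(time_ms >= wdef$window[1] & time_ms <= wdef$window[2])
    if (!length(sel)) abort_validation("waveform does not cover the ", nm, " window")
    seg <- waveform[sel]
    score <- if (polarity == "free") abs(seg) else wdef$polarity * seg
    i <- sel[which.max(score)]              # which.max returns the earliest tie
    lat <- time_ms[i]
    half <- 10
    asel <- time_ms >= lat - half & time_ms <= lat + half
    amp <- mean(waveform[asel])
    edge <- i == sel[1] || i == sel[length(sel)]
    data.frame(peak = nm, latency_ms = lat, amplitude = amp, edge_flag = edge,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Peak measures at scalp channel Fz
#'
#' Applies the same peak scoring to the Fz deviance waveform — the
#' conventional scalp comparator for the correlation audit (the deviance
#' response is maximal at frontocentral sites).
#'
#' @param erp_diff an `erp` of channel-space deviance waveforms with row
#'   names (channel labels) on `waveform`.
#' @param channel comparator channel (default `"Fz"`).
#' @inheritParams score_peaks
#' @return data.frame as [score_peaks()].
#' @export
fz_reference_measures <- function(erp_diff, channel = "Fz",
                                  windows = peak_windows(),
                                  polarity = "nominal") {
  labs <- rownames(erp_diff$waveform)
  if (is.null(labs) || !channel %in% labs)
    abort_validation("channel ", channel, " absent from the ERP set")
  score_peaks(erp_diff$waveform[channel, ], erp_diff$time_ms, windows, polarity)
}
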