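# Band-pass filtering and two-stage windowed artifact rejection: an absolute
# amplitude threshold (default +/-150 uV) and a data-improbability test
# (default >5 SD per channel, >2 SD over all channels) applied to 500-ms
# windows beginning at stimulus onsets. Rejected windows are cleared from the
# recording's retained-sample mask; events inside them are excluded from
# later epoching.

# Hamming-windowed-sinc linear-phase FIR band-pass kernel; DC gain exactly 0.
fir_bandpass_kernel <- function(lo_hz, hi_hz, fs, trans_hz = NULL) {
  trans <- trans_hz %||% max(0.5, 0.8 * lo_hz)
  L <- ceiling(3.3 * fs / trans)
  if (L %% 2 == 0) L <- L + 1
  m <- (L - 1) / 2
  k <- -m:m
  sinc_lp <- function(fc) {
    h <- 2 * fc / fs * sinc_fun(2 * fc / fs * k)
    h * (0.54 + 0.46 * cos(pi * k / m))     # Hamming
  }
  h_hi <- sinc_lp(hi_hz); h_hi <- h_hi / sum(h_hi)
  h_lo <- sinc_lp(lo_hz); h_lo <- h_lo / sum(h_lo)
  h_hi - h_lo
}

sinc_fun <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# zero-phase filtering: symmetric-kernel overlap-free FFT convolution with
# reflective padding and group-delay trim; the kernel spectrum is shared
# across channels and the FFT length padded to a 2-3-5-smooth size
filter_matrix <- function(X, h) {
  nx <- ncol(X)
  m <- (length(h) - 1) / 2
  pad <- min(m, nx - 1)
  np <- nx + 2 * pad
  N <- stats::nextn(np + length(h) - 1, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(N - length(h))))
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(nx - pad):(nx - 1)]), numeric(N - np))
    y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / N
    out[i, ] <- y[(m + pad + 1):(m + pad + nx)]
  }
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed-sinc linear-phase design (band-pass as a difference of
#' two low-passes, so DC gain is identically zero), applied by FFT
#' convolution with group-delay compensation.
#'
#' @param rec a [recording()].
#' @param lo_hz,hi_hz band edges (Hz); `0 < lo < hi < fs/2` required.
#' @return the filtered recording.
#' @export
bandpass <- function(rec, lo_hz = 1, hi_hz = 100) {
  if (lo_hz <= 0 || hi_hz <= lo_hz) abort_validation("need 0 < lo_hz < hi_hz")
  if (hi_hz >= rec$fs / 2) abort_validation("hi_hz must be below the Nyquist frequency")
  h <- fir_bandpass_kernel(lo_hz, hi_hz, rec$fs)
  out <- rec
  out$data <- filter_matrix(rec$data, h)
  rownames(out$data) <- rec$channel_names
  out
}

#' Segment a recording into stimulus-onset rejection windows
#'
#' One half-open window `[onset, onset + 0.5 fs)` per event (default 500 ms);
#' windows truncated by the end of the recording are dropped.
#'
#' @param rec a [recording()] with events.
#' @param window_ms window length (ms).
#' @return a `reject_windows`: list with `onsets` (0-based), `length_smp`,
#'   `event_index` (which event each window belongs to).
#' @export
segment_windows <- function(rec, window_ms = 500) {
  if (!length(rec$events$onsets)) abort_validation("recording has no events")
  L <- round(window_ms / 1000 * rec$fs)
  keep <- rec$events$onsets + L <= n_samples(rec)
  structure(list(onsets = rec$events$onsets[keep], length_smp = L,
                 event_index = which(keep), window_ms = window_ms),
            class = "reject_windows")
}

window_samples <- function(w, j) (w$onsets[j] + 1):(w$onsets[j] + w$length_smp)

#' Flag windows containing abnormal amplitudes
#'
#' A window is flagged iff any sample on any channel exceeds the threshold
#' in absolute value (default 150 microvolts).
#'
#' @param rec a [recording()]. @param windows from [segment_windows()].
#' @param thresh_uv threshold (microvolts).
#' @return logical vector, one flag per window.
#' @export
amplitude_flags <- function(rec, windows, thresh_uv = 150) {
  if (thresh_uv <= 0) abort_validation("thresh_uv must be positive")
  vapply(seq_along(windows$onsets), function(j) {
    any(abs(rec$data[, window_samples(windows, j)]) > thresh_uv)
  }, logical(1))
}

#' Flag windows by the data-improbability test
#'
#' Per channel, the amplitude density is estimated over all window samples
#' (histogram with Freedman-Diaconis bins, probability floored at 1e-12);
#' each window's mean negative log-density is z-scored across windows to give
#' a single-channel improbability statistic, and the channel-summed negative
#' log-densities are z-scored for the all-channel statistic. A window is
#' flagged `single` iff any channel's z exceeds `sd_single` (default 5) and
#' `all` iff the pooled z exceeds `sd_all` (default 2). The z-score of a
#' zero-variance statistic is defined as 0. Constant channels are excluded
#' with a warning.
#'
#' @param rec a [recording()]. @param windows from [segment_windows()].
#' @param sd_single,sd_all flag thresholds in SD units.
#' @return data.frame with logical columns `single` and `all`.
#' @export
improbability_flags <- function(rec, windows, sd_single = 5, sd_all = 2) {
  nw <- length(windows$onsets)
  if (nw < 20) abort_validation("need >= 20 windows to estimate densities")
  idx <- unlist(lapply(seq_len(nw), function(j) window_samples(windows, j)))
  nch <- nrow(rec$data)
  nll <- matrix(NA_real_, nw, nch)          # mean neg log density per window/channel
  for (i in seq_len(nch)) {
    x <- rec$data[i, idx]
    iqr <- stats::IQR(x)
    if (iqr == 0 || stats::sd(x) == 0) {
      warning("channel ", rec$channel_names[i],
              " is degenerate; excluded from the improbability test")
      next
    }
    bw <- 2 * iqr / length(x)^(1 / 3)       # Freedman-Diaconis
    breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
    dens <- pmax(graphics::hist(x, breaks = breaks, plot = FALSE)$density, 1e-12)
    bin <- pmin(pmax(findInterval(x, breaks), 1), length(dens))
    nld <- -log(dens[bin])
    nll[, i] <- rowMeans(matrix(nld, nrow = nw, byrow = TRUE))
  }
  ok <- colSums(is.na(nll)) == 0
  zmat <- apply(nll[, ok, drop = FALSE], 2, zscore0)
  pooled <- zscore0(rowSums(nll[, ok, drop = FALSE]))
  data.frame(single = apply(zmat, 1, max) > sd_single,
             all = pooled > sd_all)
}

#' Combine rejection flags and apply them to the retained-sample mask
#'
#' @param rec a [recording()]. @param windows from [segment_windows()].
#' @param amplitude,improb_single,improb_all per-window logical flags.
#' @param mode `"any"` (reject a window failing any criterion; the default)
#'   or `"at_least_two"` (the literal reading of rejecting windows exceeding
#'   more than one criterion).
#' @return list with the masked `recording` and a `report` (window flags,
#'   rejected count, retained standard/deviant trial counts).
#' @export
combine_and_apply <- function(rec, windows, amplitude, improb_single, improb_all,
                              mode = c("any", "at_least_two")) {
  mode <- match.arg(mode)
  votes <- cbind(amplitude, improb_single, improb_all)
  rejected <- if (mode == "any") rowSums(votes) >= 1 else rowSums(votes) >= 2
  out <- rec
  for (j in which(rejected))
    out$retained_mask[window_samples(windows, j)] <- FALSE
  ev_codes <- rec$events$codes[windows$event_index]
  report <- list(
    window_ms = windows$window_ms,
    window_onsets = windows$onsets,
    flags = data.frame(amplitude = amplitude, improbability_single = improb_single,
                       improbability_all = improb_all, rejected = rejected),
    mode = mode,
    n_rejected = sum(rejected),
    retained_standard = sum(!rejected & ev_codes == "standard"),
    retained_deviant = sum(!rejected & ev_codes == "deviant"))
  list(recording = out, report = report)
}

#' One-call preprocessing stage: band-pass then windowed rejection
#' @param rec a [recording()].
#' @param lo_hz,hi_hz band edges. @param thresh_uv amplitude threshold.
#' @param sd_single,sd_all improbability thresholds. @param mode rejection
#'   combination rule (see [combine_and_apply()]).
#' @return list with `recording` and `report`.
#' @export
preprocess <- function(rec, lo_hz = 1, hi_hz = 100, thresh_uv = 150,
                       sd_single = 5, sd_all = 2, mode = "any") {
  rec <- bandpass(rec, lo_hz, hi_hz)
  w <- segment_windows(rec)
  amp <- amplitude_flags(rec, w, thresh_uv)
  imp <- improbability_flags(rec, w, sd_single, sd_all)
  combine_and_apply(rec, w, amp, imp$single, imp$all, mode = mode)
}
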