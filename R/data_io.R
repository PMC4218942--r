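# Data model and on-disk formats: Recording / EventSequence / Montage /
# ScoreTable, EDF+ read/write with a sidecar events TSV.
#
# Conventions: sample indexing is 0-based; epochs are half-open sample
# intervals; times in ms are relative to stimulus onset. Data are stored
# channels x samples in microvolts.

#' Construct an event sequence
#'
#' Onsets are 0-based sample indices; codes label each tone as a frequent
#' standard or a rare (duration) deviant.
#'
#' @param onsets integer vector of 0-based sample indices, strictly increasing.
#' @param codes character vector, each `"standard"` or `"deviant"`.
#' @return an object of class `event_sequence`.
#' @export
event_sequence <- function(onsets, codes) {
  onsets <- as.integer(onsets)
  codes <- as.character(codes)
  if (length(onsets) != length(codes))
    abort_validation("onsets and codes must have equal length")
  if (length(onsets) > 1 && any(diff(onsets) <= 0))
    abort_validation("event onsets must be strictly increasing")
  if (length(codes) && !all(codes %in% c("standard", "deviant")))
    abort_validation("event codes must be 'standard' or 'deviant'")
  structure(list(onsets = onsets, codes = codes), class = "event_sequence")
}

#' Construct a multichannel EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names ordered channel labels (10-5 system).
#' @param events an [event_sequence()].
#' @param reference reference label; `"nose"` (the montage the pipeline
#'   assumes; no re-referencing is performed).
#' @param retained_mask logical per-sample mask surviving artifact rejection;
#'   defaults to all-true.
#' @return an object of class `recording`.
#' @export
recording <- function(data, fs, channel_names, events = event_sequence(integer(0), character(0)),
                      reference = "nose", retained_mask = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) abort_validation("fs must be positive")
  if (nrow(data) != length(channel_names))
    abort_validation("data row count (", nrow(data), ") != number of channel names (",
                     length(channel_names), ")")
  n <- ncol(data)
  if (length(events$onsets) && (min(events$onsets) < 0 || max(events$onsets) >= n))
    abort_validation("all event onsets must fall inside [0, n_samples)")
  if (is.null(retained_mask)) retained_mask <- rep(TRUE, n)
  if (length(retained_mask) != n)
    abort_validation("retained_mask length must equal n_samples")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = as.character(channel_names),
                 reference = reference, events = events,
                 retained_mask = as.logical(retained_mask)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f min), %d events (%d deviant), %.1f%% retained\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs / 60,
              length(x$events$onsets), sum(x$events$codes == "deviant"),
              100 * mean(x$retained_mask)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

# ---------------------------------------------------------------------------
# EDF+ I/O. EDF stores 16-bit little-endian integers per sample with a
# per-signal linear physical calibration. Data records of 1 s are used; the
# final record is zero-padded and the true sample count is stashed in the
# reserved header field so round trips are lossless in length.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF+ with a sidecar events TSV
#'
#' Samples are quantized to 16 bits over a per-channel physical range taken
#' from the actual signal extrema (or a fixed range via `physical_range`).
#' Events are written as a two-column TSV (`onset_sample`, `code`) so integer
#' onsets survive exactly.
#'
#' @param rec a [recording()].
#' @param edf_path,events_path output paths.
#' @param physical_range optional fixed `c(min, max)` in microvolts applied to
#'   all channels instead of per-channel extrema.
#' @return invisibly, `c(edf_path, events_path)`.
#' @export
write_recording <- function(rec, edf_path, events_path, physical_range = NULL) {
  if (!all(is.finite(rec$data))) abort_validation("recording contains non-finite samples")
  ns <- nrow(rec$data); nsamp <- ncol(rec$data)
  fs <- rec$fs
  spr <- as.integer(round(fs))          # samples per 1-s record
  if (abs(fs - spr) > 1e-9) abort_validation("EDF writer requires an integer sampling rate")
  n_rec <- as.integer(ceiling(nsamp / spr))

  if (is.null(physical_range)) {
    pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
    deg <- pmax - pmin < 1e-9
    pmin[deg] <- pmin[deg] - 1; pmax[deg] <- pmax[deg] + 1
  } else {
    pmin <- rep(physical_range[1], ns); pmax <- rep(physical_range[2], ns)
  }
  dmin <- -32767L; dmax <- 32767L   # symmetric so a symmetric range encodes 0 exactly

  con <- file(edf_path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),                         # local patient id
    edf_pad("Startdate X X X X", 80),               # local recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8), # date, time
    edf_pad(256 + 256 * ns, 8),
    edf_pad(paste0("EDF+C NSAMP=", nsamp), 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),                                # record duration (s)
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channel_names, edf_pad, "", width = 16),
    rep(edf_pad("AgAgCl electrode", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(sprintf("%.6g", pmin), edf_pad, "", width = 8),
    vapply(sprintf("%.6g", pmax), edf_pad, "", width = 8),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("HP:1Hz LP:100Hz", 80), ns),
    rep(edf_pad(spr, 8), ns),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  padded <- matrix(0, ns, n_rec * spr)
  padded[, seq_len(nsamp)] <- rec$data
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((padded[, idx, drop = FALSE] - pmin) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }

  utils::write.table(
    data.frame(onset_sample = rec$events$onsets, code = rec$events$codes),
    events_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(edf_path, events_path))
}

#' Read a recording from EDF+ plus a sidecar events TSV
#'
#' @param edf_path EDF+ file written by [write_recording()] (or any EDF with
#'   microvolt-calibrated signals and equal per-signal rates).
#' @param events_path TSV with columns `onset_sample`, `code`; `NULL` for an
#'   event-less recording.
#' @return a [recording()] with an all-true retained mask.
#' @export
read_recording <- function(edf_path, events_path = NULL) {
  con <- file(edf_path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) abort_format("unreadable EDF header (signal count)")
  rds <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- rds(16); rds(80); rds(8)
  pmin <- as.numeric(rds(8)); pmax <- as.numeric(rds(8))
  dmin <- as.numeric(rds(8)); dmax <- as.numeric(rds(8))
  rds(80)
  spr <- as.integer(rds(8)); rds(32)
  if (length(unique(spr)) != 1)
    abort_format("EDF signals with unequal sampling rates are not supported")
  spr <- spr[1]
  fs <- spr / rec_dur

  dat <- matrix(0, ns, n_rec * spr)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr, size = 2, endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr, ncol = ns)      # sample-major per signal
    dat[, ((r - 1) * spr + 1):(r * spr)] <- t(block)
  }
  for (i in seq_len(ns))
    dat[i, ] <- (dat[i, ] - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]

  nsamp <- n_rec * spr
  m <- regmatches(reserved, regexpr("NSAMP=[0-9]+", reserved))
  if (length(m)) nsamp <- as.integer(sub("NSAMP=", "", m))
  dat <- dat[, seq_len(nsamp), drop = FALSE]

  ev <- event_sequence(integer(0), character(0))
  if (!is.null(events_path)) {
    tab <- utils::read.table(events_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("onset_sample", "code") %in% names(tab)))
      abort_format("events TSV must have columns onset_sample, code")
    ev <- event_sequence(tab$onset_sample, tab$code)
  }
  recording(dat, fs, labels, events = ev)
}

# ---------------------------------------------------------------------------
# Montage

#' The built-in 68-channel 10-5/10-10 template montage
#'
#' Electrode positions are generated geometrically on a sphere: midline
#' electrodes at 18-degree steps along the nasion-inion arc, the 10% ring at
#' 72 degrees inclination, a subtemporal ring at 90 degrees, and interior
#' electrodes by equal-arc great-circle subdivision between each row's ring
#' and midline electrodes. This is a synthetic template standing in for
#' measured 10-5 positions: it is mirror-symmetric by construction and
#' adequate for a spherical head model, but it is not digitized anatomy.
#'
#' @param scalp_radius_mm radius the unit sphere is scaled to (default the
#'   head model's 92 mm scalp shell).
#' @return a `montage`: list with `channel_names` and a channels x 3 position
#'   matrix (mm, right-anterior-superior, origin at head-model center).
#' @export
montage_1005_68 <- function(scalp_radius_mm = 92) {
  sph <- function(incl_deg, az_deg) {
    th <- incl_deg * pi / 180; ph <- az_deg * pi / 180
    c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))  # x right, y anterior, z up
  }
  slerp <- function(u, v, t) {
    w <- acos(max(-1, min(1, sum(u * v))))
    if (w < 1e-12) return(u)
    (sin((1 - t) * w) * u + sin(t * w) * v) / sin(w)
  }
  pos <- list()
  midline <- list(Fpz = c(72, 0), AFz = c(54, 0), Fz = c(36, 0), FCz = c(18, 0),
                  Cz = c(0, 0), CPz = c(18, 180), Pz = c(36, 180),
                  POz = c(54, 180), Oz = c(72, 180), Iz = c(90, 180))
  for (nm in names(midline)) pos[[nm]] <- sph(midline[[nm]][1], midline[[nm]][2])
  ring_r <- list(Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
                 TP8 = 108, P8 = 126, PO8 = 144, O2 = 162)
  ring_l <- c(Fp2 = "Fp1", AF8 = "AF7", F8 = "F7", FT8 = "FT7", T8 = "T7",
              TP8 = "TP7", P8 = "P7", PO8 = "PO7", O2 = "O1")
  for (nm in names(ring_r)) {
    pos[[nm]] <- sph(72, ring_r[[nm]])
    pos[[ring_l[[nm]]]] <- sph(72, -ring_r[[nm]])
  }
  low <- list(F10 = 54, T10 = 90, P10 = 126)
  low_l <- c(F10 = "F9", T10 = "T9", P10 = "P9")
  for (nm in names(low)) {
    pos[[nm]] <- sph(90, low[[nm]])
    pos[[low_l[[nm]]]] <- sph(90, -low[[nm]])
  }
  interp_row <- function(mid, ring_right, ring_left, nums_right, nums_left, fracs, prefix) {
    for (i in seq_along(fracs)) {
      pos[[paste0(prefix, nums_right[i])]] <<- slerp(pos[[mid]], pos[[ring_right]], fracs[i])
      pos[[paste0(prefix, nums_left[i])]] <<- slerp(pos[[mid]], pos[[ring_left]], fracs[i])
    }
  }
  interp_row("Fz", "F8", "F7", c(2, 4, 6), c(1, 3, 5), c(.25, .5, .75), "F")
  interp_row("FCz", "FT8", "FT7", c(2, 4, 6), c(1, 3, 5), c(.25, .5, .75), "FC")
  interp_row("Cz", "T8", "T7", c(2, 4, 6), c(1, 3, 5), c(.25, .5, .75), "C")
  interp_row("CPz", "TP8", "TP7", c(2, 4, 6), c(1, 3, 5), c(.25, .5, .75), "CP")
  interp_row("Pz", "P8", "P7", c(2, 4, 6), c(1, 3, 5), c(.25, .5, .75), "P")
  interp_row("AFz", "AF8", "AF7", 4, 3, 0.5, "AF")
  interp_row("POz", "PO8", "PO7", 4, 3, 0.5, "PO")

  names_ord <- names(pos)
  mat <- do.call(rbind, pos) * scalp_radius_mm
  rownames(mat) <- names_ord
  structure(list(channel_names = names_ord, positions = mat,
                 scalp_radius_mm = scalp_radius_mm),
            class = "montage")
}

#' Load an electrode montage
#'
#' @param source the built-in montage name `"template-68"`, or the path of a
#'   whitespace-delimited electrode-position file (`name x y z` per line, mm).
#' @param scalp_radius_mm positions are rescaled so the outermost electrode
#'   sits at this radius (registration of the montage to the head model).
#' @return a `montage`.
#' @export
load_montage <- function(source = "template-68", scalp_radius_mm = 92) {
  if (identical(source, "template-68")) return(montage_1005_68(scalp_radius_mm))
  if (!file.exists(source)) abort_validation("unknown montage: ", source)
  tab <- utils::read.table(source, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("name", "x", "y", "z"))
  if (anyDuplicated(tab$name)) abort_validation("duplicate channel labels in montage file")
  mat <- as.matrix(tab[, c("x", "y", "z")])
  rownames(mat) <- tab$name
  r <- sqrt(rowSums(mat^2))
  if (any(r == 0)) abort_validation("electrode at origin in montage file")
  mat <- mat * (scalp_radius_mm / max(r))
  structure(list(channel_names = tab$name, positions = mat,
                 scalp_radius_mm = scalp_radius_mm), class = "montage")
}

#' Restrict a montage to a subset of channels (test profiles)
#' @param montage a `montage`.
#' @param channels channel labels to keep, in the given order.
#' @return a `montage` with the selected channels.
#' @export
montage_subset <- function(montage, channels) {
  miss <- setdiff(channels, montage$channel_names)
  if (length(miss)) abort_validation("unknown channel label(s): ", paste(miss, collapse = ", "))
  structure(list(channel_names = channels,
                 positions = montage$positions[channels, , drop = FALSE],
                 scalp_radius_mm = montage$scalp_radius_mm), class = "montage")
}

# ---------------------------------------------------------------------------
# Score tables

#' Read a per-subject clinical/cognitive score table
#'
#' @param path TSV with columns `subject_id`, `group` (NCS or SZ) and one
#'   column per named score; empty cells are missing values.
#' @return a data.frame; subject ids are checked unique.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!all(c("subject_id", "group") %in% names(tab)))
    abort_format("score table must have subject_id and group columns")
  if (anyDuplicated(tab$subject_id)) abort_validation("subject_id values must be unique")
  if (any(is.na(tab$group) | tab$group == "")) abort_validation("group must be non-empty")
  tab
}

#' Write a score table as TSV
#' @param scores data.frame as from [read_score_table()].
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
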