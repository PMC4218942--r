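# Forward-model synthetic oddball-EEG generator. Emulates the duration-
# deviant paradigm (1-kHz tones, 500-ms onset asynchrony, 50-ms standards at
# p = 0.90, 100-ms deviants at p = 0.10, >= 6 standards between deviants,
# 500 Hz sampling) with planted dipolar brain sources carrying triphasic
# MMN-P3a-RON deviance responses, artifact processes (blinks, EMG bursts,
# line noise), sensor noise, group amplitude effects, and clinical scores
# coupled to planted peak amplitudes at configurable r-squared.

#' Specify a planted cortical source
#'
#' @param name source label.
#' @param location 3-D position (mm, head-model frame); must lie inside the
#'   brain shell.
#' @param orientation dipole moment direction (normalized internally).
#' @param background list with `exponent` (1/f slope of the background
#'   spectrum) and `osc` (list of `list(hz=, amp=)` oscillation peaks),
#'   and `amp` (overall background RMS in source units).
#' @param deviance_peaks list of `list(label=, latency_ms=, width_ms=,
#'   amp=c(NCS=, SZ=))` Gaussian bumps added to deviant-tone responses only.
#'   Amplitudes are in source units; MMN/RON bumps are negative, P3a positive.
#' @param standard_response optional same-shaped bump added to every tone
#'   (a small N1-like response shared by standards and deviants).
#' @return a `source_spec`.
#' @export
source_spec <- function(name, location, orientation,
                        background = list(exponent = 1, amp = 1, osc = list()),
                        deviance_peaks = list(),
                        standard_response = NULL) {
  orientation <- orientation / sqrt(sum(orientation^2))
  for (pk in deviance_peaks)
    if (pk$width_ms <= 0) abort_validation("peak widths must be positive")
  structure(list(name = name, location = location, orientation = orientation,
                 background = background, deviance_peaks = deviance_peaks,
                 standard_response = standard_response),
            class = "source_spec")
}

#' Default six-source deviance roster plus background brain sources
#'
#' The six deviance-carrying sources follow the cluster roster of the
#' analysis this generator emulates (right superior temporal, right inferior
#' frontal, ventral mid-cingulate, anterior cingulate, medial orbitofrontal,
#' dorsal mid-cingulate). Coordinates are plausible template-space defaults
#' chosen by the implementer, NOT published values. MMN latencies are
#' staggered across sources within 153-223 ms; each source carries a full
#' triphasic complex whose SZ-group amplitudes are scaled down per source,
#' most strongly for the mid-cingulate sources.
#'
#' @param n_background number of additional background-only brain sources
#'   (no event-locked response) scattered through the brain shell, giving
#'   ICA and the dipolarity screen realistic work; default 14 for a
#'   20-source brain model.
#' @param seed seed for the background-source placement.
#' @return list of `source_spec`.
#' @export
default_sources <- function(n_background = 14, seed = 99) {
  rost <- list(
    list("R Superior Temporal",  c(55, -25, 10), c(0.8, 0.3, 0.5),  155, 0.95),
    list("R Inferior Frontal",   c(45, 28, 12),  c(0.7, 0.5, 0.5),  165, 0.70),
    list("Ventral Mid-Cingulate", c(2, -8, 38),  c(0.1, 0.4, 0.9),  180, 0.55),
    list("Anterior Cingulate",   c(2, 32, 22),   c(0.1, 0.6, 0.8),  195, 0.65),
    list("Medial Orbitofrontal", c(2, 42, -8),   c(0.1, 0.8, -0.6), 210, 0.60),
    list("Dorsal Mid-Cingulate", c(2, -15, 46),  c(0.1, -0.3, 0.95), 223, 0.50))
  # source units are calibrated against the forward model: unit-moment maps
  # peak near 100 microvolts, so a background amplitude of ~0.12 source units
  # contributes ~5 uV scalp RMS per source (total background ~20-30 uV over
  # a 20-source brain) and peak amplitudes of a few times 0.01 give a summed
  # frontocentral deviance response of a few microvolts
  mk <- function(r) {
    lat_mmn <- r[[4]]; sz <- r[[5]]
    amp <- function(a) c(NCS = a, SZ = a * sz)
    source_spec(r[[1]], r[[2]], r[[3]],
      background = list(exponent = 1, amp = 0.12,
                        osc = list(list(hz = 10, amp = 0.5))),
      deviance_peaks = list(
        list(label = "MMN", latency_ms = lat_mmn, width_ms = 25, amp = amp(-0.012)),
        list(label = "P3a", latency_ms = 280, width_ms = 30, amp = amp(0.010)),
        list(label = "RON", latency_ms = 380, width_ms = 35, amp = amp(-0.008))),
      standard_response = list(latency_ms = 100, width_ms = 20,
                               amp = c(NCS = -0.004, SZ = -0.004)))
  }
  sources <- lapply(rost, mk)
  if (n_background > 0) {
    set.seed(seed)
    k <- 0
    while (k < n_background) {
      p <- stats::runif(3, -60, 60)
      if (sqrt(sum(p^2)) > 70 || sqrt(sum(p^2)) < 20) next
      k <- k + 1
      sources[[length(sources) + 1]] <- source_spec(
        paste0("Background-", k), p, stats::rnorm(3),
        background = list(exponent = 1, amp = 0.12,
                          osc = if (k %% 2) list(list(hz = 10, amp = 0.6)) else list()))
    }
  }
  sources
}

#' Cohort configuration for the synthetic oddball paradigm
#'
#' Defaults state the emulated paradigm: 500-ms onset asynchrony, deviant
#' probability 0.10 with at least 6 standards between deviants, 500 Hz,
#' 20-minute sessions, 68-channel 10-5 montage, 47 NCS and 42 SZ subjects.
#'
#' @param n_ncs,n_sz subjects per group.
#' @param fs sampling rate (Hz). @param session_min session length (minutes).
#' @param soa_ms stimulus onset asynchrony (ms). @param p_deviant deviant
#'   probability. @param min_standards_between minimum run of standards
#'   between deviants.
#' @param montage a `montage` (default the built-in 68-channel template).
#' @param sources list of `source_spec` (default [default_sources()]).
#' @param artifacts list: `blink_per_min`, `blink_amp_uv`, `emg_per_min`,
#'   `emg_amp_uv`, `line_hz`, `line_amp_uv`.
#' @param sensor_noise_sd_uv white sensor noise SD per channel (microvolts).
#' @param jitter list of inter-subject jitter SDs: `location_mm`,
#'   `amp_frac`, `latency_ms`.
#' @param couplings list of `list(score = , source = , peak = , r2 = ,
#'   group = )` couplings of clinical scores to realized peak amplitudes.
#' @param score_names clinical/cognitive score columns to simulate.
#' @param head_model a [head_model()] shared with the localization stage.
#' @param seed cohort master seed.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_ncs = 47, n_sz = 42, fs = 500, session_min = 20,
                          soa_ms = 500, p_deviant = 0.10, min_standards_between = 6,
                          montage = montage_1005_68(),
                          sources = default_sources(),
                          artifacts = list(blink_per_min = 4, blink_amp_uv = 350,
                                           emg_per_min = 2, emg_amp_uv = 40,
                                           line_hz = 60, line_amp_uv = 3),
                          sensor_noise_sd_uv = 4,
                          jitter = list(location_mm = 4, amp_frac = 0.4,
                                        latency_ms = 8),
                          couplings = list(),
                          score_names = c("SANS", "SAPS", "GAF", "SOF", "UPSA",
                                          "WRAT", "CVLT_imm", "CVLT_del",
                                          "WCST", "LNS"),
                          head_model = devsource::head_model(),
                          seed = 1) {
  if (p_deviant < 0 || p_deviant >= 1) abort_validation("p_deviant must lie in [0, 1)")
  if (min_standards_between < 0) abort_validation("min_standards_between must be >= 0")
  for (cp in couplings)
    if (cp$r2 < 0 || cp$r2 >= 1) abort_validation("coupling target r2 must lie in [0, 1)")
  rb <- head_model$radii_mm[1]
  for (s in sources)
    if (sqrt(sum(s$location^2)) >= rb)
      abort_validation("source '", s$name, "' lies outside the brain shell")
  structure(list(n_ncs = n_ncs, n_sz = n_sz, fs = fs, session_min = session_min,
                 soa_ms = soa_ms, p_deviant = p_deviant,
                 min_standards_between = min_standards_between,
                 montage = montage, sources = sources, artifacts = artifacts,
                 sensor_noise_sd_uv = sensor_noise_sd_uv, jitter = jitter,
                 couplings = couplings, score_names = score_names,
                 head_model = head_model, seed = seed),
            class = "cohort_config")
}

#' A reduced test-profile configuration
#'
#' 31 channels, short sessions, small groups: the same stated world at a
#' desk-testable scale.
#' @param ... overrides passed to [cohort_config()].
#' @export
test_profile_config <- function(...) {
  mon <- montage_subset(montage_1005_68(), c(
    "Fp1", "Fp2", "Fpz", "AFz", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FCz", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CPz", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "POz", "Oz"))
  args <- list(n_ncs = 10, n_sz = 10, session_min = 5, montage = mon,
               sources = default_sources(n_background = 6))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

#' Generate a pseudorandom oddball event sequence
#'
#' Deviants are drawn so that at least `min_standards_between` standards
#' separate consecutive deviants; the post-run deviant hazard is set to
#' `p / (1 - p * min)` so the empirical deviant fraction converges to
#' `p_deviant` despite the run constraint.
#'
#' @param n_tones number of tones. @param p_deviant deviant probability.
#' @param min_standards_between minimum standards between deviants.
#' @param seed integer seed.
#' @return character vector of codes (`"standard"`/`"deviant"`).
#' @export
generate_event_codes <- function(n_tones, p_deviant = 0.10,
                                 min_standards_between = 6, seed = 1) {
  if (n_tones < 1) abort_validation("n_tones must be >= 1")
  if (p_deviant > 1 / (1 + min_standards_between))
    abort_validation("p_deviant and min_standards_between are jointly infeasible")
  if (p_deviant == 0) return(rep("standard", n_tones))
  q <- p_deviant / (1 - p_deviant * min_standards_between)
  set.seed(seed)
  codes <- character(n_tones)
  since <- min_standards_between             # allow an early deviant
  u <- stats::runif(n_tones)
  for (i in seq_len(n_tones)) {
    if (since >= min_standards_between && u[i] < q) {
      codes[i] <- "deviant"; since <- 0
    } else {
      codes[i] <- "standard"; since <- since + 1
    }
  }
  codes
}

#' @rdname generate_event_codes
#' @param fs sampling rate (Hz). @param soa_ms onset asynchrony (ms).
#' @return `generate_event_sequence`: an [event_sequence()] with onsets at
#'   multiples of the onset asynchrony.
#' @export
generate_event_sequence <- function(n_tones, p_deviant = 0.10,
                                    min_standards_between = 6, seed = 1,
                                    fs = 500, soa_ms = 500) {
  codes <- generate_event_codes(n_tones, p_deviant, min_standards_between, seed)
  onsets <- round(seq(0, by = soa_ms / 1000 * fs, length.out = n_tones))
  event_sequence(onsets, codes)
}

# 1/f + oscillation background, unit RMS, by spectral shaping of white noise.
# A slow log-normal amplitude-modulation envelope (mod_sd > 0) makes the
# marginal super-Gaussian, as cortical source activity is -- without it the
# sources would be Gaussian and unidentifiable by ICA.
background_signal <- function(n, fs, exponent, osc, mod_sd = 0.6) {
  shape_noise <- function(shape_fun) {
    w <- stats::rnorm(n)
    f <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
    shape <- shape_fun(f)
    W <- stats::fft(w)
    full <- c(shape, rev(shape[2:(n - length(shape) + 1)]))
    Re(stats::fft(W * full, inverse = TRUE)) / n
  }
  x <- shape_noise(function(f) {
    s <- c(0, 1 / (f[-1]^(exponent / 2)))
    for (o in osc) s <- s + o$amp * exp(-0.5 * ((f - o$hz) / 1.5)^2)
    s
  })
  if (mod_sd > 0) {
    env <- shape_noise(function(f) as.numeric(f < 1) * exp(-f))  # slow drive
    if (stats::sd(env) > 0) {
      env <- exp(mod_sd * env / stats::sd(env))
      x <- x * env
    }
  }
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

gaussian_bump <- function(t_ms, latency_ms, width_ms, amp)
  amp * exp(-0.5 * ((t_ms - latency_ms) / width_ms)^2)

# event-locked response template on 0..resp_ms for one source and group,
# deviant and standard variants; lat_shift/amp_scale carry subject jitter
response_templates <- function(src, group, fs, lat_shift, amp_scale, resp_ms = 500) {
  t_ms <- seq(0, resp_ms, by = 1000 / fs)
  std <- numeric(length(t_ms))
  if (!is.null(src$standard_response)) {
    sr <- src$standard_response
    std <- gaussian_bump(t_ms, sr$latency_ms, sr$width_ms, sr$amp[[group]])
  }
  dev <- std
  realized <- list()
  for (pk in src$deviance_peaks) {
    lat <- pk$latency_ms + lat_shift
    amp <- pk$amp[[group]] * amp_scale
    dev <- dev + gaussian_bump(t_ms, lat, pk$width_ms, amp)
    realized[[pk$label]] <- list(latency_ms = lat, amp = amp, width_ms = pk$width_ms)
  }
  list(std = std, dev = dev, realized = realized)
}

#' Generate one synthetic subject
#'
#' Channel data are the sum of forward-projected brain sources (1/f
#' background plus event-locked responses), artifact processes, and white
#' sensor noise; the linear mixing model and every realized parameter are
#' returned as ground truth.
#'
#' @param config a [cohort_config()].
#' @param subject_id subject label. @param group `"NCS"` or `"SZ"`.
#' @param seed subject seed (derive via [substream_seed()] for cohorts).
#' @return list with `recording` and `truth` (realized source parameters,
#'   mixing matrix, source/artifact time courses' scalp maps, artifact times).
#' @export
generate_subject <- function(config, subject_id, group, seed = 1) {
  set.seed(seed)
  fs <- config$fs
  n <- round(config$session_min * 60 * fs)
  soa_smp <- config$soa_ms / 1000 * fs
  n_tones <- floor((n - fs) / soa_smp)       # leave a tail for the last epoch
  ev <- generate_event_sequence(n_tones, config$p_deviant,
                                config$min_standards_between,
                                seed = seed + 1, fs = fs, soa_ms = config$soa_ms)
  mon <- config$montage
  hm <- config$head_model
  nch <- length(mon$channel_names)
  data <- matrix(0, nch, n)

  jit <- config$jitter
  truth_sources <- list()
  maps <- NULL
  src_names <- character(0)
  for (si in seq_along(config$sources)) {
    src <- config$sources[[si]]
    loc <- src$location + stats::rnorm(3, 0, jit$location_mm)
    rb <- hm$radii_mm[1]
    if (sqrt(sum(loc^2)) >= 0.95 * rb) loc <- loc * (0.9 * rb / sqrt(sum(loc^2)))
    lat_shift <- stats::rnorm(1, 0, jit$latency_ms)
    amp_scale <- max(0.1, 1 + stats::rnorm(1, 0, jit$amp_frac))
    map <- dipole_potential(loc, src$orientation, hm, mon)

    s_t <- src$background$amp * background_signal(n, fs, src$background$exponent,
                                                  src$background$osc)
    tmpl <- response_templates(src, group, fs, lat_shift, amp_scale)
    L <- length(tmpl$std)
    for (k in seq_along(ev$onsets)) {
      i0 <- ev$onsets[k] + 1
      idx <- i0:min(i0 + L - 1, n)
      r <- if (ev$codes[k] == "deviant") tmpl$dev else tmpl$std
      s_t[idx] <- s_t[idx] + r[seq_along(idx)]
    }
    data <- data + outer(map, s_t)
    maps <- cbind(maps, map)
    src_names <- c(src_names, src$name)
    truth_sources[[src$name]] <- list(
      location = loc, orientation = src$orientation,
      lat_shift_ms = lat_shift, amp_scale = amp_scale,
      realized_peaks = tmpl$realized, map = map)
  }

  art <- config$artifacts
  artifact_times <- list()
  # blinks: smooth ~300-ms biphasic frontal deflection at Poisson times; the
  # scalp pattern is a bilateral periocular falloff (a non-dipolar map, as
  # real blink projections are for a brain-shell dipole model)
  n_blink <- stats::rpois(1, art$blink_per_min * config$session_min)
  eye_l <- c(-28, 98, -38); eye_r <- c(28, 98, -38)
  d_l <- sqrt(rowSums(sweep(mon$positions, 2, eye_l)^2))
  d_r <- sqrt(rowSums(sweep(mon$positions, 2, eye_r)^2))
  blink_map <- 1 / d_l^2 + 1 / d_r^2          # near-field periocular falloff
  blink_map <- blink_map / max(blink_map)
  blink_t <- numeric(n)
  if (n_blink > 0) {
    times <- sort(stats::runif(n_blink, 0, n - fs))
    artifact_times$blink_samples <- round(times)
    tt <- seq(0, 0.4, by = 1 / fs)
    shape <- sin(pi * tt / 0.4)^2 * (1 - 0.3 * sin(2 * pi * tt / 0.4))
    for (tb in round(times)) {
      idx <- (tb + 1):min(tb + length(shape), n)
      blink_t[idx] <- blink_t[idx] + shape[seq_along(idx)]
    }
  }
  data <- data + art$blink_amp_uv * outer(blink_map, blink_t)

  # EMG: shallow temporal patches with 20-100 Hz band-limited bursts
  emg_sites <- list(c(88, 10, -18), c(-88, 10, -18))
  emg_maps <- vapply(emg_sites, function(p) {
    d <- sqrt(rowSums(sweep(mon$positions, 2, p)^2))
    m <- 1 / d^2; m / max(m)                   # near-field muscle patch
  }, numeric(nch))
  n_emg <- stats::rpois(1, art$emg_per_min * config$session_min)
  emg_t <- matrix(0, 2, n)
  if (n_emg > 0) {
    times <- sort(stats::runif(n_emg, 0, n - fs))
    artifact_times$emg_samples <- round(times)
    L <- round(0.5 * fs)
    for (tb in round(times)) {
      side <- sample(1:2, 1)
      idx <- (tb + 1):min(tb + L, n)
      burst <- background_signal(length(idx), fs, 0, list(), mod_sd = 0)  # white
      bf <- stats::fft(burst)
      f <- seq(0, fs, length.out = length(idx) + 1)[seq_along(idx)]
      f <- pmin(f, fs - f)
      bf[f < 20 | f > 100] <- 0
      burst <- Re(stats::fft(bf, inverse = TRUE)) / length(idx)
      if (stats::sd(burst) > 0) burst <- burst / stats::sd(burst)
      taper <- sin(pi * seq_along(idx) / length(idx))^2
      emg_t[side, idx] <- emg_t[side, idx] + burst * taper
    }
  }
  data <- data + art$emg_amp_uv * emg_maps %*% emg_t

  # line noise: common sinusoid
  line_t <- sin(2 * pi * art$line_hz * seq_len(n) / fs)
  data <- data + art$line_amp_uv * outer(rep(1, nch), line_t)

  if (config$sensor_noise_sd_uv > 0)
    data <- data + matrix(stats::rnorm(nch * n, 0, config$sensor_noise_sd_uv), nch, n)

  mixing <- cbind(maps, blink_map, emg_maps, rep(1, nch))
  colnames(mixing) <- c(src_names, "blink", "emg_l", "emg_r", "line")
  rec <- recording(data, fs, mon$channel_names, events = ev)
  list(recording = rec,
       truth = list(subject_id = subject_id, group = group, seed = seed,
                    sources = truth_sources, mixing = mixing,
                    artifact_times = artifact_times))
}

# population-r2 coupling: score = center + slope * amp + noise, with noise
# variance sd_amp^2 * slope^2 * (1 - r2) / r2 so the population squared
# correlation equals r2
couple_score <- function(amps, r2, center = 50, slope = 1) {
  if (r2 < 0 || r2 >= 1) abort_validation("target r2 must lie in [0, 1)")
  base <- center + slope * (amps - mean(amps))
  if (r2 == 0) return(center + stats::rnorm(length(amps), 0, max(stats::sd(amps), 1)))
  sd_noise <- stats::sd(amps) * abs(slope) * sqrt((1 - r2) / r2)
  base + stats::rnorm(length(amps), 0, sd_noise)
}

#' Generate a full synthetic cohort
#'
#' Per-subject random streams derive from the cohort seed and subject index,
#' so cohorts are reproducible subject-wise. Clinical scores are independent
#' noise except where a coupling ties them to a source's realized peak
#' amplitude at a target population r-squared.
#'
#' @param config a [cohort_config()].
#' @return list with `recordings` (named list), `scores` (data.frame),
#'   `truth` (per-subject ground truth plus realized couplings).
#' @export
generate_cohort <- function(config) {
  subjects <- c(sprintf("NCS%02d", seq_len(config$n_ncs)),
                sprintf("SZ%02d", seq_len(config$n_sz)))
  groups <- c(rep("NCS", config$n_ncs), rep("SZ", config$n_sz))
  src_names <- vapply(config$sources, `[[`, "", "name")
  for (cp in config$couplings) {
    if (!cp$source %in% src_names)
      abort_validation("coupling references unknown source: ", cp$source)
    if (!cp$score %in% config$score_names)
      abort_validation("coupling references unknown score: ", cp$score)
  }
  recs <- list(); truths <- list()
  for (i in seq_along(subjects)) {
    sub <- generate_subject(config, subjects[i], groups[i],
                            seed = substream_seed(config$seed, "subject", i))
    recs[[subjects[i]]] <- sub$recording
    truths[[subjects[i]]] <- sub$truth
  }
  scores <- data.frame(subject_id = subjects, group = groups,
                       stringsAsFactors = FALSE)
  set.seed(substream_seed(config$seed, "scores"))
  for (sc in config$score_names)
    scores[[sc]] <- stats::rnorm(length(subjects), 50, 10)
  realized_couplings <- list()
  for (cp in config$couplings) {
    in_grp <- if (is.null(cp$group)) rep(TRUE, length(subjects)) else groups == cp$group
    amps <- vapply(truths[in_grp], function(tr)
      tr$sources[[cp$source]]$realized_peaks[[cp$peak]]$amp, numeric(1))
    scores[[cp$score]][in_grp] <- couple_score(amps, cp$r2)
    realized_couplings[[length(realized_couplings) + 1]] <-
      c(cp, list(latent_amps = amps))
  }
  list(recordings = recs, scores = scores,
       truth = list(subjects = truths, couplings = realized_couplings,
                    config_seed = config$seed))
}

#' Build ground-truth IC records for a cohort (clustering validation)
#'
#' Constructs the across-subject [ic_record()] set a perfect decomposition
#' would deliver: for each subject and each deviance-carrying source, the
#' subject's jittered dipole is forward-projected (plus optional map noise)
#' and re-fit with [fit_dipole()]; spectra follow the source's background
#' shape and ERPs its planted response templates. This isolates the
#' clustering stage from ICA estimation error, which is validated
#' separately.
#'
#' @param config a [cohort_config()].
#' @param map_noise relative RMS of white noise added to each scalp map.
#' @param erp_noise SD of noise on the ERP templates (source units).
#' @param seed integer seed.
#' @param fit_starts dipole-fit multi-starts.
#' @return list with `records` (list of `ic_record`) and `source_id`
#'   (integer ground-truth source index per record).
#' @export
build_truth_ic_records <- function(config, map_noise = 0.05, erp_noise = 0.05,
                                   seed = 1, fit_starts = 3) {
  subjects <- c(sprintf("NCS%02d", seq_len(config$n_ncs)),
                sprintf("SZ%02d", seq_len(config$n_sz)))
  groups <- c(rep("NCS", config$n_ncs), rep("SZ", config$n_sz))
  mon <- config$montage
  hm <- config$head_model
  jit <- config$jitter
  freq <- seq(3, 50, length.out = 24)
  t_ms <- seq(0, 500, by = 1000 / config$fs)
  records <- list()
  source_id <- integer(0)
  dev_sources <- which(vapply(config$sources, function(s)
    length(s$deviance_peaks) > 0, logical(1)))
  for (i in seq_along(subjects)) {
    set.seed(substream_seed(seed, "truthrec", i))
    for (si in dev_sources) {
      src <- config$sources[[si]]
      loc <- src$location + stats::rnorm(3, 0, jit$location_mm)
      rb <- hm$radii_mm[1]
      if (sqrt(sum(loc^2)) >= 0.95 * rb) loc <- loc * (0.9 * rb / sqrt(sum(loc^2)))
      map <- dipole_potential(loc, src$orientation, hm, mon)
      map <- map + stats::rnorm(length(map), 0, map_noise * sqrt(mean(map^2)))
      map <- map / sqrt(sum(map^2))
      fit <- fit_dipole(map, hm, mon, n_starts = fit_starts,
                        seed = substream_seed(seed, "truthfit", i, si))
      shape <- 1 / freq^(src$background$exponent / 2)
      for (o in src$background$osc)
        shape <- shape + o$amp * exp(-0.5 * ((freq - o$hz) / 1.5)^2)
      spec <- 10 * log10(shape^2) + stats::rnorm(length(freq), 0, 0.5)
      tmpl <- response_templates(src, groups[i], config$fs,
                                 stats::rnorm(1, 0, jit$latency_ms),
                                 max(0.1, 1 + stats::rnorm(1, 0, jit$amp_frac)))
      records[[length(records) + 1]] <- ic_record(
        subjects[i], groups[i], si, map, fit, spec,
        tmpl$std[seq_along(t_ms)] + stats::rnorm(length(t_ms), 0, erp_noise),
        tmpl$dev[seq_along(t_ms)] + stats::rnorm(length(t_ms), 0, erp_noise))
      source_id <- c(source_id, si)
    }
  }
  list(records = records, source_id = source_id)
}

#' Simulate a cohort at the peak-measurement level
#'
#' A lightweight stand-in for the full recording chain used to validate the
#' statistical stages at scale: per subject, each source's deviance waveform
#' is its planted triphasic bump complex with subject jitter plus residual
#' trial-averaged ERP noise; peaks are then scored by the same
#' [score_peaks()] used on real waveforms, and clinical scores are coupled to
#' the realized (latent) peak amplitudes exactly as in [generate_cohort()].
#' The ICA/localization chain is validated separately by parameter recovery;
#' this shortcut inherits its calibration, not its errors.
#'
#' @param config a [cohort_config()] (sources, jitter, couplings are used).
#' @param erp_noise_sd residual noise SD of the averaged deviance waveform in
#'   source units; the default is the generator's single-trial background
#'   amplitude over the square root of the ~215 retained deviant trials of a
#'   default session (0.12/sqrt(215) = 0.008).
#' @param seed cohort seed.
#' @return list with `peak_table` (subject, group, source, peak, latency_ms,
#'   amplitude), `scores`, and `latent` (realized amplitudes per coupling).
#' @export
simulate_peak_cohort <- function(config, erp_noise_sd = 0.12 / sqrt(215),
                                 seed = config$seed) {
  subjects <- c(sprintf("NCS%02d", seq_len(config$n_ncs)),
                sprintf("SZ%02d", seq_len(config$n_sz)))
  groups <- c(rep("NCS", config$n_ncs), rep("SZ", config$n_sz))
  fs <- config$fs
  t_ms <- seq(-100, 500, by = 1000 / fs)
  jit <- config$jitter
  rows <- list()
  latent <- list()
  for (i in seq_along(subjects)) {
    set.seed(substream_seed(seed, "peakcohort", i))
    for (src in config$sources) {
      if (!length(src$deviance_peaks)) next
      lat_shift <- stats::rnorm(1, 0, jit$latency_ms)
      amp_scale <- max(0.1, 1 + stats::rnorm(1, 0, jit$amp_frac))
      wav <- stats::rnorm(length(t_ms), 0, erp_noise_sd)
      for (pk in src$deviance_peaks) {
        lat <- pk$latency_ms + lat_shift
        amp <- pk$amp[[groups[i]]] * amp_scale
        wav <- wav + gaussian_bump(t_ms, lat, pk$width_ms, amp)
        latent[[src$name]][[pk$label]] <-
          c(latent[[src$name]][[pk$label]], stats::setNames(amp, subjects[i]))
      }
      scored <- score_peaks(wav, t_ms)
      scored$subject <- subjects[i]; scored$group <- groups[i]
      scored$source <- src$name
      rows[[length(rows) + 1]] <- scored
    }
  }
  peak_table <- do.call(rbind, rows)
  scores <- data.frame(subject_id = subjects, group = groups,
                       stringsAsFactors = FALSE)
  set.seed(substream_seed(seed, "peakcohort-scores"))
  for (sc in config$score_names)
    scores[[sc]] <- stats::rnorm(length(subjects), 50, 10)
  for (cp in config$couplings) {
    in_grp <- if (is.null(cp$group)) rep(TRUE, length(subjects)) else groups == cp$group
    amps <- latent[[cp$source]][[cp$peak]][subjects[in_grp]]
    scores[[cp$score]][in_grp] <- couple_score(amps, cp$r2)
  }
  list(peak_table = peak_table, scores = scores, latent = latent)
}

#' Write a cohort to disk (EDF+ + events TSV + scores TSV + truth JSON)
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings))
    write_recording(cohort$recordings[[id]],
                    file.path(dir, paste0(id, ".edf")),
                    file.path(dir, paste0(id, "_events.tsv")))
  write_score_table(cohort$scores, file.path(dir, "scores.tsv"))
  truth <- rapply(cohort$truth, function(x) if (is.matrix(x)) as.data.frame(x) else x,
                  how = "replace")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  invisible(dir)
}
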