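test_that("event sequences honor probability and the standards-run constraint", {
  expect_true(all(generate_event_codes(100, 0) == "standard"))
  expect_error(generate_event_codes(100, 0.2, 6),
               class = "devsource_validation_error")

  codes <- generate_event_codes(2400, 0.10, 6, seed = 5)
  ndev <- sum(codes == "deviant")
  expect_gte(ndev, 200)
  expect_lte(ndev, 280)
  # exhaustively: no 7-tone window contains two deviants
  dev <- codes == "deviant"
  win2 <- vapply(seq_len(length(dev) - 6), function(i) sum(dev[i:(i + 6)]) >= 2,
                 logical(1))
  expect_false(any(win2))

  # property over seeds: constraint and convergence hold for every sequence
  for (s in 1:10) {
    cd <- generate_event_codes(3000, 0.10, 6, seed = s)
    gaps <- diff(which(cd == "deviant"))
    expect_true(all(gaps >= 7))
  }
  frac <- mean(generate_event_codes(5e4, 0.10, 6, seed = 1) == "deviant")
  expect_lt(abs(frac - 0.10), 0.01)
})

test_that("event sequence onsets follow the onset asynchrony", {
  ev <- generate_event_sequence(50, 0.1, 6, seed = 1, fs = 500, soa_ms = 500)
  expect_equal(diff(ev$onsets), rep(250, 49))
})

test_that("generated data follow the linear mixing model", {
  cfg <- test_profile_config(session_min = 0.5,
                             sources = default_sources(n_background = 2))
  sub <- generate_subject(cfg, "T1", "NCS", seed = 4)
  # 8 brain sources + blink + 2 EMG patches + line noise
  expect_identical(dim(sub$truth$mixing),
                   c(length(cfg$montage$channel_names), 12L))
  # a silent configuration produces an all-zero recording
  quiet <- cfg
  quiet$sources <- list(source_spec("off", c(0, 0, 40), c(0, 0, 1),
                                    background = list(exponent = 1, amp = 0,
                                                      osc = list())))
  quiet$artifacts <- list(blink_per_min = 0, blink_amp_uv = 0, emg_per_min = 0,
                          emg_amp_uv = 0, line_hz = 60, line_amp_uv = 0)
  quiet$sensor_noise_sd_uv <- 0
  zsub <- generate_subject(quiet, "T1", "NCS", seed = 4)
  expect_equal(max(abs(zsub$recording$data)), 0)
})

test_that("a single noiseless source projects exactly through the head model", {
  cfg <- test_profile_config(session_min = 0.5)
  cfg$sources <- list(source_spec("solo", c(30, 20, 40), c(0, 1, 1),
    background = list(exponent = 1, amp = 0.1, osc = list())))
  cfg$artifacts <- list(blink_per_min = 0, blink_amp_uv = 0, emg_per_min = 0,
                        emg_amp_uv = 0, line_hz = 60, line_amp_uv = 0)
  cfg$sensor_noise_sd_uv <- 0
  cfg$jitter <- list(location_mm = 0, amp_frac = 0, latency_ms = 0)
  sub <- generate_subject(cfg, "T1", "NCS", seed = 9)
  tr <- sub$truth$sources[["solo"]]
  map <- dipole_potential(tr$location, tr$orientation, cfg$head_model, cfg$montage)
  # at every instant the scalp map is the forward projection times the source
  X <- sub$recording$data
  s_hat <- as.numeric(crossprod(map, X) / sum(map^2))
  expect_lt(max(abs(X - outer(map, s_hat))), 1e-8 * max(abs(X)))
})

test_that("planted deviance shows as a frontocentral negativity in the MMN window", {
  cfg <- test_profile_config(session_min = 3)
  sub <- generate_subject(cfg, "T1", "NCS", seed = 11)
  rec <- sub$recording
  e_s <- epoch_and_average(rec$data, rec$fs, rec$events, "standard")
  e_d <- epoch_and_average(rec$data, rec$fs, rec$events, "deviant")
  d <- deviance_response(e_d, e_s)
  sel <- d$time_ms >= 140 & d$time_ms <= 240
  fcz <- colMeans(d$waveform[c("Fz", "FCz", "Cz"), sel])
  expect_lt(min(fcz), -1)   # clear negativity (microvolts)
})

test_that("score couplings hit their target population r-squared", {
  # r2 = 0: score independent of peak amplitude
  set.seed(1)
  r2s <- replicate(200, {
    amps <- rnorm(40, -3, 1)
    cor(amps, devsource:::couple_score(amps, 0))^2
  })
  expect_gte(mean(r2s < 0.1), 0.95)
  # r2 = 0.48 against the latent amplitudes, mean over replicate cohorts
  set.seed(2)
  r2c <- replicate(200, {
    amps <- rnorm(42, -3, 1)
    cor(amps, devsource:::couple_score(amps, 0.48))^2
  })
  expect_lt(abs(mean(r2c) - 0.48), 0.05)
})

test_that("group amplitude scaling is exact in the ground truth", {
  cfg <- test_profile_config(session_min = 0.5,
                             sources = default_sources(n_background = 0))
  cfg$jitter <- list(location_mm = 0, amp_frac = 0, latency_ms = 0)
  a <- generate_subject(cfg, "N1", "NCS", seed = 3)
  b <- generate_subject(cfg, "S1", "SZ", seed = 3)
  rat <- b$truth$sources[["Dorsal Mid-Cingulate"]]$realized_peaks$MMN$amp /
    a$truth$sources[["Dorsal Mid-Cingulate"]]$realized_peaks$MMN$amp
  expect_equal(rat, 0.50)
})

test_that("cohorts are reproducible subject-wise and write/read cleanly", {
  cfg <- test_profile_config(session_min = 0.25, n_ncs = 1, n_sz = 1,
                             sources = default_sources(n_background = 0))
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$recordings[["SZ01"]]$data, co2$recordings[["SZ01"]]$data)
  expect_identical(co1$scores, co2$scores)
  dir <- withr::local_tempdir()
  write_cohort(co1, dir)
  expect_true(file.exists(file.path(dir, "NCS01.edf")))
  expect_true(file.exists(file.path(dir, "scores.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_recording(file.path(dir, "SZ01.edf"),
                         file.path(dir, "SZ01_events.tsv"))
  expect_identical(back$events$codes, co1$recordings[["SZ01"]]$events$codes)
})
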