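test_that("epoching averages, subtracts the post-average baseline, and counts trials", {
  fs <- 500
  n <- 5000
  ev <- event_sequence(seq(100, 4500, by = 500), rep("standard", 9))
  # identical epochs: ERP equals one epoch minus its baseline mean
  tmpl <- sin(2 * pi * 7 * seq_len(n) / fs) + 2
  x <- matrix(tmpl, 1)
  e <- epoch_and_average(x, fs, ev, "standard")
  expect_identical(e$n_trials, 9L)
  bl <- e$time_ms <= 0
  expect_lt(abs(mean(e$waveform[1, bl])), 1e-9)
  one <- x[1, (ev$onsets[1] - 50 + 1):(ev$onsets[1] + 251)]
  expect_equal(e$waveform[1, ], one - mean(one[1:51]), tolerance = 1e-9)
  # averaging law on white noise
  set.seed(3)
  ev2 <- event_sequence(seq(60, by = 300, length.out = 400), rep("deviant", 400))
  xr <- matrix(rnorm(400 * 300 + 1000), 1)
  e2 <- epoch_and_average(xr, fs, ev2, "deviant")
  expect_lt(abs(sd(e2$waveform[1, ]) - 1 / sqrt(400)) / (1 / sqrt(400)), 0.25)
  # zero retained trials errors with the condition named
  expect_error(epoch_and_average(x, fs, ev, "deviant"), "deviant")
  # retained mask excludes events
  mask <- rep(TRUE, n); mask[ev$onsets + 1] <- FALSE
  expect_error(epoch_and_average(x, fs, ev, "standard", retained_mask = mask),
               "standard")
})

test_that("deviance response is the pointwise condition difference", {
  fs <- 500
  ev <- event_sequence(c(seq(100, 2000, by = 500), seq(2350, 4000, by = 500)),
                       rep(c("standard", "deviant"), c(4, 4)))
  x <- matrix(rnorm(2, 0, 0) + 1, 1, 5000)
  bump <- exp(-0.5 * ((seq(-50, 250) / 500 * 1000 - 180) / 25)^2)
  for (o in ev$onsets[ev$codes == "deviant"])
    x[1, (o - 50 + 1):(o + 251)] <- x[1, (o - 50 + 1):(o + 251)] - 2 * bump
  e_s <- epoch_and_average(x, fs, ev, "standard")
  e_d <- epoch_and_average(x, fs, ev, "deviant")
  d <- deviance_response(e_d, e_s)
  target <- -2 * (bump - mean(bump[1:51]))
  expect_equal(d$waveform[1, ], target, tolerance = 1e-9)
  expect_equal(deviance_response(e_s, e_s)$waveform[1, ], rep(0, 301))
  e_bad <- e_s; e_bad$time_ms <- e_bad$time_ms + 2
  expect_error(deviance_response(e_d, e_bad), "time base")
})

test_that("back-projection respects sign indeterminacy and single-channel maps", {
  # single IC with a unit map at one channel
  map <- matrix(c(0, 1, 0, 0), 4, 1)
  wav <- matrix(sin(seq(0, 2 * pi, length.out = 50)), 1)
  bp <- backproject(map, wav)
  expect_equal(bp$channel_waveforms[2, ], wav[1, ])
  expect_equal(bp$channel_waveforms[1, ], rep(0, 50))
  # RMS over 4 channels with one active = |wav|/2, signed at the max-map channel
  expect_equal(bp$trace, wav[1, ] / 2, tolerance = 1e-9)
  # flipping one member's map and waveform together changes nothing
  set.seed(5)
  maps <- matrix(rnorm(8), 4, 2)
  wavs <- matrix(rnorm(100), 2, 50)
  bp1 <- backproject(maps, wavs)
  maps2 <- maps; wavs2 <- wavs
  maps2[, 2] <- -maps2[, 2]; wavs2[2, ] <- -wavs2[2, ]
  bp2 <- backproject(maps2, wavs2)
  expect_equal(bp1$channel_waveforms, bp2$channel_waveforms)
  expect_equal(bp1$trace, bp2$trace)
  # empty membership
  bp0 <- backproject(matrix(numeric(0), 4, 0), matrix(numeric(0), 0, 50))
  expect_true(all(bp0$channel_waveforms == 0))
})

test_that("pvaf endpoints, negativity, and windowing follow the formula", {
  set.seed(6)
  total <- matrix(rnorm(4 * 100), 4)
  expect_equal(pvaf(total, total), 100)
  expect_equal(pvaf(total * 0, total), 0)
  # orthogonal equal-variance component gives -100
  a <- matrix(c(1, -1, 0, 0), 1)
  b <- matrix(c(0, 0, 1, -1), 1)
  expect_equal(pvaf(b, a), -100)
  expect_error(pvaf(total * 0, total * 0), "zero")
  # window restriction
  tm <- seq(-100, 500, length.out = 100)
  in_w <- tm >= 0 & tm <= 500
  expect_equal(pvaf(total, total + 0, time_ms = tm),
               pvaf(total[, in_w], (total + 0)[, in_w]))
})

test_that("peak scoring finds planted bumps with exact latency and 20-ms mean amplitude", {
  fs <- 500
  tm <- seq(-100, 500, by = 1000 / fs)
  gauss <- function(lat, wid, amp) amp * exp(-0.5 * ((tm - lat) / wid)^2)
  wav <- gauss(190, 20, -2) + gauss(280, 25, 1.5) + gauss(390, 25, -1.2)
  pk <- score_peaks(wav, tm)
  expect_equal(pk$latency_ms, c(190, 280, 390))
  # closed-form 20-ms Gaussian mean around the peak
  mmn_mean <- integrate(function(t) -2 * exp(-0.5 * ((t - 190) / 20)^2),
                        180, 200)$value / 20
  expect_lt(abs(pk$amplitude[1] - mmn_mean) / abs(mmn_mean), 0.01)
  expect_false(any(pk$edge_flag))
  # latency equivariance under small shifts
  sh <- 10
  wav2 <- gauss(190 + sh, 20, -2) + gauss(280 + sh, 25, 1.5) + gauss(390 + sh, 25, -1.2)
  pk2 <- score_peaks(wav2, tm)
  expect_equal(pk2$latency_ms, pk$latency_ms + sh)
  # zero waveform: tie rule picks window start, edge flagged, amplitude 0
  pk0 <- score_peaks(rep(0, length(tm)), tm)
  expect_equal(pk0$latency_ms, c(140, 220, 310))
  expect_true(all(pk0$edge_flag))
  expect_equal(pk0$amplitude, c(0, 0, 0))
  # windows are the documented defaults
  w <- peak_windows()
  expect_equal(w$MMN$window, c(140, 240))
  expect_equal(w$P3a$window, c(220, 340))
  expect_equal(w$RON$window, c(310, 460))
})

test_that("Fz reference measures score the Fz channel and demand its presence", {
  fs <- 500
  tm <- seq(-100, 500, by = 1000 / fs)
  wav <- -2 * exp(-0.5 * ((tm - 200) / 20)^2)
  W <- rbind(Fz = wav, Cz = 0.5 * wav)
  e <- structure(list(time_ms = tm, waveform = W, condition = "deviance"),
                 class = "erp")
  pk <- fz_reference_measures(e)
  expect_equal(pk, score_peaks(wav, tm))
  rownames(e$waveform) <- c("F1", "Cz")
  expect_error(fz_reference_measures(e), "Fz")
})
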