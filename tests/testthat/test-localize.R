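test_that("forward model matches the independent double-truncation oracle to 1e-8", {
  hm <- fix_hm
  dip_pos <- c(0, 36, 48)                    # radial-ish, 60 mm eccentricity
  dip_pos <- dip_pos / sqrt(sum(dip_pos^2)) * 60
  for (mom in list(dip_pos / 60, c(1, 0, 0), c(0.3, -0.5, 0.8))) {
    v_main <- dipole_potential(dip_pos, mom, hm, fix_mon68)
    v_oracle <- oracle_potential(dip_pos, mom, hm, fix_mon68, order = 2 * hm$order)
    expect_lt(max(abs(v_main - v_oracle)) / max(abs(v_oracle)), 1e-8)
  }
})

test_that("shell coefficients reduce to the homogeneous closed form and satisfy the BVP", {
  hm_h <- head_model(conductivities = c(0.33, 0.33, 0.33))
  n <- seq_len(hm_h$order)
  expect_equal(hm_h$coef, (2 * n + 1) / n, tolerance = 1e-12)
  # interface continuity residuals of the 3-shell solution
  sig <- c(0.33, 0.0042, 0.33)
  radii <- c(80, 85, 92)
  r1 <- radii[1] / radii[3]; r2 <- radii[2] / radii[3]
  for (n in c(1, 5, 20, 40)) {
    m <- matrix(0, 5, 5); b <- numeric(5)
    m[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0); b[1] <- -r1^(-(n + 1))
    m[2, ] <- c(sig[1] * n * r1^(n - 1), -sig[2] * n * r1^(n - 1),
                sig[2] * (n + 1) * r1^(-(n + 2)), 0, 0)
    b[2] <- sig[1] * (n + 1) * r1^(-(n + 2))
    m[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    m[4, ] <- c(0, sig[2] * n * r2^(n - 1), -sig[2] * (n + 1) * r2^(-(n + 2)),
                -sig[3] * n * r2^(n - 1), sig[3] * (n + 1) * r2^(-(n + 2)))
    m[5, ] <- c(0, 0, 0, sig[3] * n, -sig[3] * (n + 1))
    x <- solve(m, b)
    expect_lt(max(abs(m %*% x - b)), 1e-9)
  }
})

test_that("forward model is linear in the moment and symmetric for central dipoles", {
  v1 <- dipole_potential(c(20, -10, 30), c(1, 2, -1), fix_hm, fix_mon68)
  v2 <- dipole_potential(c(20, -10, 30), 2 * c(1, 2, -1), fix_hm, fix_mon68)
  expect_equal(v2, 2 * v1)
  # central +z dipole: value depends only on electrode z-angle; mirrored
  # electrodes in x carry identical potentials
  vz <- dipole_potential(c(0, 0, 0), c(0, 0, 1), fix_hm, fix_mon68)
  names(vz) <- fix_mon68$channel_names
  expect_lt(abs(vz[["F3"]] - vz[["F4"]]), 1e-6 * max(abs(vz)))
  expect_error(dipole_potential(c(0, 0, 90), c(0, 0, 1), fix_hm, fix_mon68),
               class = "devsource_validation_error")
})

test_that("noiseless forward-fit round trips recover position and moment", {
  set.seed(21)
  for (rep in 1:5) {
    pos <- runif(3, -1, 1); pos <- pos / sqrt(sum(pos^2)) * runif(1, 10, 70)
    mom <- rnorm(3)
    map <- dipole_potential(pos, mom, fix_hm, fix_mon68)
    fit <- fit_dipole(map, fix_hm, fix_mon68, n_starts = 6, seed = rep)
    expect_lt(sqrt(sum((fit$position - pos)^2)), 1)
    expect_lt(fit$rv, 1e-4)
    expect_lt(max(abs(fit$moment - mom)) / max(abs(mom)), 0.05)
    # negated map: same position, negated moment
    fitn <- fit_dipole(-map, fix_hm, fix_mon68, n_starts = 6, seed = rep)
    expect_lt(sqrt(sum((fitn$position - pos)^2)), 1.5)
    expect_lt(max(abs(fitn$moment + fit$moment)), 1e-3 * max(abs(fit$moment)))
  }
})

test_that("rv is scale-invariant and noisy maps stay within the dipolarity screen", {
  pos <- c(30, 20, 50); mom <- c(1, -1, 2)
  map <- dipole_potential(pos, mom, fix_hm, fix_mon68)
  f1 <- fit_dipole(map, fix_hm, fix_mon68, n_starts = 4, seed = 1)
  f2 <- fit_dipole(10 * map, fix_hm, fix_mon68, n_starts = 4, seed = 1)
  expect_equal(f1$rv, f2$rv, tolerance = 1e-8)
  set.seed(33)
  for (rep in 1:10) {
    noisy <- map + rnorm(length(map), 0, 0.1 * sqrt(mean(map^2)))
    fit <- fit_dipole(noisy, fix_hm, fix_mon68, n_starts = 4, seed = rep)
    expect_gt(fit$rv, 0); expect_lt(fit$rv, 0.15)
    expect_lt(sqrt(sum((fit$position - pos)^2)), 10)
  }
})

test_that("the dipolarity/inside-brain screen applies both criteria", {
  mkfit <- function(rv, pos) structure(list(position = pos, moment = c(0, 0, 1),
                                            rv = rv,
                                            inside_brain = sqrt(sum(pos^2)) < 80),
                                       class = "dipole_fit")
  fits <- list(mkfit(0.16, c(0, 0, 10)),   # fails dipolarity
               mkfit(0, c(0, 0, 0)),       # retained
               mkfit(0.05, c(0, 0, 85)),   # outside brain
               mkfit(0.149, c(10, 10, 10)))
  expect_identical(screen_ics(fits), c(2L, 4L))
  expect_identical(screen_ics(fits, require_inside = FALSE), c(2L, 3L, 4L))
})

test_that("planted brain sources pass the screen, periocular/muscle maps fail it", {
  cfg <- test_profile_config()
  brain_maps <- lapply(default_sources(n_background = 0)[1:3], function(s)
    dipole_potential(s$location, s$orientation, cfg$head_model, cfg$montage))
  eye <- c(28, 98, -38)
  d <- sqrt(rowSums(sweep(cfg$montage$positions, 2, eye)^2))
  blink <- 1 / d^2
  fits <- lapply(c(brain_maps, list(blink)), function(m)
    fit_dipole(m, cfg$head_model, cfg$montage, n_starts = 6, seed = 2))
  expect_identical(screen_ics(fits), 1:3)
  expect_false(fits[[4]]$inside_brain)
})
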