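# Shared fixtures, all generated in code (no binary files).

# small montage + head model reused across tests
fix_hm <- head_model()
fix_mon31 <- test_profile_config()$montage
fix_mon68 <- montage_1005_68()

# a tiny deterministic recording with events
make_test_recording <- function(nch = 4, n = 1500, fs = 500, seed = 42,
                                sd = 20) {
  set.seed(seed)
  ev <- event_sequence(seq(50, n - 300, by = 250),
                       rep(c("standard", "standard", "deviant"), length.out =
                             length(seq(50, n - 300, by = 250))))
  recording(matrix(rnorm(nch * n, 0, sd), nch, n), fs,
            c("Fz", "Cz", "Pz", "Oz", "F3", "F4", "C3", "C4")[seq_len(nch)],
            events = ev)
}

# deterministic Laplacian sources mixed by a random matrix
make_mixed_laplacian <- function(m = 2, n = 2e4, seed = 7) {
  set.seed(seed)
  S <- matrix(rexp(m * n) * sign(runif(m * n, -1, 1)), m)
  A <- matrix(rnorm(m * m), m)
  list(X = A %*% S, A = A, S = S)
}

# tiny clustering fixture: well-separated blobs in feature space
make_blob_records <- function(n_per = 8, centers = list(c(30, 20, 40),
                                                        c(-30, 20, 40),
                                                        c(0, -40, 30)),
                              seed = 3) {
  set.seed(seed)
  records <- list()
  truth <- integer(0)
  for (b in seq_along(centers)) {
    for (i in seq_len(n_per)) {
      pos <- centers[[b]] + rnorm(3, 0, 1)
      map <- dipole_potential(pos, rnorm(3), fix_hm, fix_mon31)
      map <- map / sqrt(sum(map^2))
      fit <- structure(list(position = pos, moment = c(0, 0, 1), rv = 0.01,
                            inside_brain = TRUE), class = "dipole_fit")
      records[[length(records) + 1]] <- ic_record(
        sprintf("S%02d", i), if (i %% 2) "NCS" else "SZ", b, map, fit,
        spectrum = rnorm(20) + b, erp_std = rnorm(10), erp_dev = rnorm(10) + b)
      truth <- c(truth, b)
    }
  }
  list(records = records, truth = truth)
}

# independent forward-model oracle: direct per-electrode partial-sum
# evaluation of the shell series (scalar loops, no vectorized Legendre
# table), at arbitrary truncation order
oracle_potential <- function(position, moment, hm, montage, order) {
  cn <- devsource:::shell_coefficients(hm$radii_mm, hm$conductivities, order)
  R <- hm$radii_mm[3]
  b <- sqrt(sum(position^2))
  bhat <- if (b > 1e-9) position / b else c(0, 0, 1)
  f <- b / R
  sapply(seq_len(nrow(montage$positions)), function(e) {
    rhat <- montage$positions[e, ] / sqrt(sum(montage$positions[e, ]^2))
    u <- max(-1, min(1, sum(rhat * bhat)))
    tvec <- rhat - u * bhat
    v <- 0
    for (n in seq_len(order)) {
      Pn <- legendreP_scalar(n, u)
      dPn <- legendreP_deriv_scalar(n, u)
      v <- v + cn[n] * f^(n - 1) *
        (n * Pn * sum(moment * bhat) + dPn * sum(moment * tvec))
    }
    v / (4 * pi * hm$conductivities[1] * (R / 1000)^2)
  })
}
legendreP_scalar <- function(n, x) {
  p0 <- 1; p1 <- x
  if (n == 0) return(p0)
  if (n == 1) return(p1)
  for (k in 2:n) { p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k; p0 <- p1; p1 <- p2 }
  p1
}
legendreP_deriv_scalar <- function(n, x) {
  if (n == 0) return(0)
  if (abs(abs(x) - 1) < 1e-12) x <- sign(x) * (1 - 1e-12)
  (n / (1 - x^2)) * (legendreP_scalar(n - 1, x) - x * legendreP_scalar(n, x))
}

# cluster purity against known labels
purity <- function(assign, truth) {
  ok <- !is.na(assign)
  tab <- table(assign[ok], truth[ok])
  sum(apply(tab, 1, max)) / sum(tab)
}
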