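test_that("Spearman correlation matches a brute-force rank oracle and handles ties", {
  x <- c(3, 1, 4, 1, 5, 9)
  y <- c(2, 7, 1, 8, 2, 8)
  res <- spearman(x, y)
  # independent oracle: explicit average-rank formula
  rx <- rank(x); ry <- rank(y)
  r_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$n_pairs, 6L)
  # monotone pairs
  expect_equal(spearman(1:8, exp(1:8))$r, 1)
  expect_equal(spearman(1:8, -(1:8)^3)$r, -1)
  expect_equal(spearman(1:8, exp(1:8))$r2, 1)
  # missing values deleted pairwise
  res2 <- spearman(c(x, NA), c(y, 5))
  expect_equal(res2$n_pairs, 6L)
  expect_error(spearman(1:4, 1:4), "pairs")
  expect_error(spearman(rep(1, 6), 1:6), "constant")
})

test_that("critical r-squared inversion reproduces the published thresholds", {
  expect_equal(round(critical_r2(0.05, 30, 42), 2), 0.22)
  expect_gte(critical_r2(0.05, 180, 42), 0.28)
  # consistency: threshold vanishes as n grows
  r2s <- vapply(c(50, 100, 1000, 10000), function(n) critical_r2(0.05, 30, n),
                numeric(1))
  expect_true(all(diff(r2s) < 0))
  expect_lt(r2s[4], 0.005)
  expect_error(critical_r2(0.05, 30, 3), class = "devsource_validation_error")
  expect_error(critical_r2(1.2, 1, 42), class = "devsource_validation_error")
})

test_that("critical r2 agrees with a permutation null within 0.02", {
  set.seed(71)
  n <- 42
  x <- rnorm(n); y <- rnorm(n)
  rx <- rank(x)
  r2perm <- replicate(2e4, cor(rx, sample(rank(y)))^2)
  alpha <- 0.05 / 30
  q <- unname(stats::quantile(r2perm, 1 - alpha))
  expect_lt(abs(q - critical_r2(0.05, 30, n)), 0.02)
})

test_that("expected significant counts: analytic matches Monte-Carlo within 3 SE", {
  ana <- expected_significant(60, 0.10, 42, method = "analytic")
  mc <- expected_significant(60, 0.10, 42, method = "montecarlo",
                             n_rep = 2e4, seed = 2)
  expect_lt(abs(ana - mc), 3 * attr(mc, "se"))
  # monotone in tau and in n
  taus <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  es <- vapply(taus, function(t) expected_significant(60, t, 42), numeric(1))
  expect_true(all(diff(es) < 0))
  en <- vapply(c(20, 42, 100), function(n) expected_significant(60, 0.10, n),
               numeric(1))
  expect_true(all(diff(en) < 0))
  expect_lt(expected_significant(60, 0.999, 42), 1e-10)
})

test_that("group contrasts compute Welch t and pooled-SD Cohen's d", {
  pt <- data.frame(
    subject = c(sprintf("N%02d", 1:40), sprintf("S%02d", 1:40)),
    group = rep(c("NCS", "SZ"), each = 40),
    source = "C01", peak = "MMN",
    latency_ms = rep(190, 80),
    amplitude = c(rnorm(40, 1, 1), rnorm(40, 0, 1)))
  set.seed(8)
  pt$amplitude <- c(scale(rnorm(40)) * 1 + 1, scale(rnorm(40)) * 1 + 0)
  gc <- group_contrasts(pt)
  d <- gc$cohens_d[gc$measure == "amplitude"]
  expect_equal(d, 1.0, tolerance = 1e-9)
  # identical groups: d = 0, t = 0
  pt2 <- pt; pt2$amplitude <- rep(c(1, 2), 40)
  gc2 <- group_contrasts(pt2)
  expect_equal(gc2$cohens_d[gc2$measure == "amplitude"], 0)
})

test_that("audit family sizes, Bonferroni flags and stratum counts are coherent", {
  set.seed(9)
  subj <- sprintf("S%02d", 1:42)
  peaks <- c("MMN", "P3a", "RON")
  sources <- c("Fz", sprintf("C%02d", 1:6))
  pt <- expand.grid(subject = subj, source = sources, peak = peaks,
                    stringsAsFactors = FALSE)
  pt$group <- "SZ"
  pt$amplitude <- rnorm(nrow(pt))
  pt$latency_ms <- rnorm(nrow(pt), 200, 20)
  st <- data.frame(subject_id = subj, group = "SZ")
  for (v in sprintf("V%02d", 1:10)) st[[v]] <- rnorm(42)
  aud <- correlation_audit(pt, st)
  expect_equal(unname(aud$family_sizes), c(30, 180))  # peaks x vars, + x sources
  expect_equal(round(aud$critical_r2[["Fz"]], 2), 0.22)
  expect_gte(aud$critical_r2[["source"]], 0.28)
  expect_equal(nrow(aud$pairs), 2 * (30 + 180))
  s <- aud$strata
  for (fam in c("Fz", "source")) {
    sf <- s[s$family == fam, ]
    expect_true(all(diff(sf$observed_total) <= 0))
    expect_true(all(diff(sf$expected) < 0))
  }
  expect_equal(s$n_tests[s$family == "Fz"][1], 60)
  expect_equal(s$n_tests[s$family == "source"][1], 360)
})

test_that("audit is invariant under monotone transforms of the scores", {
  set.seed(10)
  subj <- sprintf("S%02d", 1:30)
  pt <- expand.grid(subject = subj, source = c("Fz", "C01"), peak = "MMN",
                    stringsAsFactors = FALSE)
  pt$group <- "SZ"; pt$amplitude <- rnorm(nrow(pt)); pt$latency_ms <- rnorm(nrow(pt))
  st <- data.frame(subject_id = subj, group = "SZ", V1 = rnorm(30), V2 = runif(30))
  a1 <- correlation_audit(pt, st)
  st2 <- st; st2$V1 <- exp(st$V1); st2$V2 <- st$V2^3
  a2 <- correlation_audit(pt, st2)
  expect_equal(a1$pairs$r, a2$pairs$r, tolerance = 1e-12)
  expect_equal(a1$strata$observed_total, a2$strata$observed_total)
})

test_that("null scores produce observed counts consistent with expectation", {
  # moderate Monte-Carlo: 60-test Fz-like family across simulated cohorts
  set.seed(11)
  counts <- replicate(100, {
    subj <- sprintf("S%02d", 1:42)
    pt <- expand.grid(subject = subj, source = "Fz",
                      peak = c("MMN", "P3a", "RON"), stringsAsFactors = FALSE)
    pt$group <- "SZ"; pt$amplitude <- rnorm(nrow(pt)); pt$latency_ms <- rnorm(nrow(pt))
    st <- data.frame(subject_id = subj, group = "SZ")
    for (v in sprintf("V%02d", 1:10)) st[[v]] <- rnorm(42)
    aud <- correlation_audit(pt, st, strata = 0.10)
    aud$strata$observed_total
  })
  expected <- expected_significant(60, 0.10, 42)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})
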