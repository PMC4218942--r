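# Group contrasts, the Spearman correlation screen with the 10%-variance
# rule, Bonferroni critical-r-squared inversion, and the expected-versus-
# observed significant-correlation audit stratified by r-squared magnitude.

#' Spearman rank correlation with the t-approximation p-value
#'
#' Average ranks for ties; missing values removed pairwise; two-sided p from
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param min_pairs minimum complete pairs (default 5).
#' @return list with `r`, `r2`, `p`, `n_pairs`.
#' @export
spearman <- function(x, y, min_pairs = 5) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_pairs) abort_validation("fewer than ", min_pairs, " complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_validation("correlation undefined for a constant vector")
  r <- stats::cor(rank(x), rank(y))
  r2 <- r^2
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(n - 2) / sqrt(1 - r2)
    2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, r2 = r2, p = p, n_pairs = n)
}

#' Bonferroni critical r-squared by inverting the t-approximation
#'
#' Per-test level `alpha_family / n_tests` (two-sided); the critical
#' correlation is \eqn{r^* = t^*/\sqrt{t^{*2} + n - 2}} with
#' \eqn{t^* = t_{1-\alpha/2, n-2}}.
#'
#' @param alpha_family family-wise level (default 0.05).
#' @param n_tests number of tests in the family.
#' @param n sample size (> 3).
#' @return critical r-squared.
#' @export
critical_r2 <- function(alpha_family = 0.05, n_tests = 1, n = 42) {
  if (n <= 3) abort_validation("n must exceed 3")
  if (n_tests < 1) abort_validation("n_tests must be >= 1")
  alpha <- alpha_family / n_tests
  if (alpha / 2 >= 0.5) abort_validation("per-test alpha/2 must be below 0.5")
  tstar <- stats::qt(1 - alpha / 2, df = n - 2)
  tstar^2 / (tstar^2 + n - 2)
}

#' Expected number of significant correlations under the null
#'
#' `method = "analytic"`: `n_tests` times the two-sided tail probability of
#' exceeding \eqn{r^2 = \tau} under the t-approximation with n-2 df.
#' `method = "montecarlo"`: mean count over `n_rep` simulated independent
#' Gaussian pairs scored by the same Spearman screen.
#'
#' @param n_tests family size. @param tau r-squared stratum threshold.
#' @param n sample size. @param method `"analytic"` or `"montecarlo"`.
#' @param n_rep Monte-Carlo replicates. @param seed Monte-Carlo seed.
#' @return expected count; for `"montecarlo"`, with attribute `se` (the
#'   Monte-Carlo standard error of the count).
#' @export
expected_significant <- function(n_tests, tau, n = 42,
                                 method = c("analytic", "montecarlo"),
                                 n_rep = 1e5, seed = 1) {
  method <- match.arg(method)
  if (tau <= 0 || tau >= 1) abort_validation("tau must lie in (0, 1)")
  if (method == "analytic") {
    t_tau <- sqrt(tau) * sqrt(n - 2) / sqrt(1 - tau)
    p_tau <- 2 * stats::pt(t_tau, n - 2, lower.tail = FALSE)
    return(n_tests * p_tau)
  }
  set.seed(seed)
  X <- matrix(stats::rnorm(n * n_rep), n)
  Y <- matrix(stats::rnorm(n * n_rep), n)
  RX <- apply(X, 2, rank); RY <- apply(Y, 2, rank)
  RX <- sweep(RX, 2, colMeans(RX)); RY <- sweep(RY, 2, colMeans(RY))
  r <- colSums(RX * RY) / sqrt(colSums(RX^2) * colSums(RY^2))
  hits <- r^2 > tau
  out <- n_tests * mean(hits)
  attr(out, "se") <- n_tests * stats::sd(hits) / sqrt(n_rep)
  out
}

#' Welch group contrasts with Cohen's d per source and peak
#'
#' Replaces the original mixed-model analysis with per-cell two-sample
#' contrasts: Welch t on amplitudes and latencies per (source, peak), with
#' pooled-SD Cohen's d signed NCS minus SZ. Subjects missing from a source
#' are excluded pairwise.
#'
#' @param peak_table data.frame with columns subject, group, source, peak,
#'   latency_ms, amplitude.
#' @return data.frame of contrasts (one row per source x peak x measure).
#' @export
group_contrasts <- function(peak_table) {
  cells <- unique(peak_table[, c("source", "peak")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- peak_table[peak_table$source == cells$source[i] &
                      peak_table$peak == cells$peak[i], ]
    for (meas in c("amplitude", "latency_ms")) {
      a <- sub[[meas]][sub$group == "NCS"]
      b <- sub[[meas]][sub$group == "SZ"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        warning("cell ", cells$source[i], "/", cells$peak[i], " has < 2 per group; skipped")
        next
      }
      sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
      d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
      tt <- if (stats::sd(a) == 0 && stats::sd(b) == 0)
        list(statistic = 0, p.value = 1)
      else stats::t.test(a, b)
      rows[[length(rows) + 1]] <- data.frame(
        source = cells$source[i], peak = cells$peak[i], measure = meas,
        mean_NCS = mean(a), sd_NCS = stats::sd(a), n_NCS = length(a),
        mean_SZ = mean(b), sd_SZ = stats::sd(b), n_SZ = length(b),
        welch_t = unname(tt$statistic), p = tt$p.value, cohens_d = d,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Observed-versus-expected significant-correlation audit
#'
#' Computes every (measure, clinical variable) Spearman pair within the Fz
#' family and the source-cluster family, separately for amplitudes and
#' latencies; tabulates observed counts per r-squared stratum against
#' analytic chance expectations (expected counts pool the amplitude and
#' latency tests: 2 x peaks x variables for Fz, 2 x sources x peaks x
#' variables for clusters), and flags pairs exceeding the per-measure-type
#' Bonferroni critical r-squared (alpha / (peaks x variables [x sources])).
#'
#' @param peak_table data.frame with columns subject, group, source
#'   (`"Fz"` or a cluster label), peak, latency_ms, amplitude.
#' @param score_table data.frame with subject_id, group, and score columns.
#' @param variables score columns to audit (default: all non-id columns).
#' @param group audited group (default `"SZ"`, the clinical audit).
#' @param strata r-squared thresholds.
#' @param alpha family-wise level.
#' @param min_pairs minimum complete pairs per correlation.
#' @return a `correlation_audit`: `pairs` (per-pair r, r2, p, n, flags),
#'   `strata` (per family x measure type observed counts and pooled expected
#'   counts), `critical_r2` per family, `family_sizes`.
#' @export
correlation_audit <- function(peak_table, score_table,
                              variables = NULL, group = "SZ",
                              strata = c(0.10, 0.20, 0.30, 0.40, 0.50),
                              alpha = 0.05, min_pairs = 5) {
  variables <- variables %||%
    setdiff(names(score_table), c("subject_id", "group"))
  if (!length(variables)) abort_validation("no clinical variables to audit")
  pt <- peak_table[peak_table$group == group, ]
  st <- score_table[score_table$group == group, ]
  sources <- setdiff(unique(pt$source), "Fz")
  peaks <- unique(pt$peak)
  n_fz <- length(peaks) * length(variables)
  n_src <- length(sources) * length(peaks) * length(variables)
  crit <- c(Fz = if (n_fz) critical_r2(alpha, n_fz, max(nrow(st), 4)) else NA,
            source = if (n_src) critical_r2(alpha, n_src, max(nrow(st), 4)) else NA)

  rows <- list()
  for (src in unique(pt$source)) {
    fam <- if (src == "Fz") "Fz" else "source"
    for (pk in peaks) {
      cell <- pt[pt$source == src & pt$peak == pk, ]
      m <- match(st$subject_id, cell$subject)
      for (meas in c("amplitude", "latency_ms")) {
        vals <- cell[[meas]][m]
        for (v in variables) {
          res <- tryCatch(spearman(vals, st[[v]], min_pairs),
                          error = function(e) NULL)
          if (is.null(res)) next
          rows[[length(rows) + 1]] <- data.frame(
            family = fam, source = src, peak = pk,
            measure_type = if (meas == "amplitude") "amplitude" else "latency",
            variable = v, n = res$n_pairs, r = res$r, r2 = res$r2, p = res$p,
            bonferroni = res$r2 > crit[[fam]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- do.call(rbind, rows)

  n_sub <- stats::median(pairs$n)
  strata_rows <- list()
  for (fam in unique(pairs$family)) {
    n_tests <- 2 * if (fam == "Fz") n_fz else n_src
    for (tau in strata) {
      sub <- pairs[pairs$family == fam, ]
      strata_rows[[length(strata_rows) + 1]] <- data.frame(
        family = fam, tau = tau, n_tests = n_tests,
        expected = expected_significant(n_tests, tau, n_sub),
        observed_amplitude = sum(sub$r2 > tau & sub$measure_type == "amplitude"),
        observed_latency = sum(sub$r2 > tau & sub$measure_type == "latency"),
        observed_total = sum(sub$r2 > tau), stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = pairs, strata = do.call(rbind, strata_rows),
                 critical_r2 = crit,
                 family_sizes = c(Fz = n_fz, source = n_src),
                 alpha = alpha, group = group, n = n_sub),
            class = "correlation_audit")
}

#' @export
print.correlation_audit <- function(x, ...) {
  cat(sprintf("<correlation_audit> group %s, n = %d; families: Fz (%d tests/measure), source (%d)\n",
              x$group, x$n, x$family_sizes["Fz"], x$family_sizes["source"]))
  cat(sprintf("critical r2: Fz %.2f, source %.2f (alpha = %g)\n",
              x$critical_r2["Fz"], x$critical_r2["source"], x$alpha))
  print(x$strata, row.names = FALSE)
  invisible(x)
}
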