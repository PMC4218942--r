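# Three-shell spherical head model with a closed-form Legendre-series forward
# solution, single equivalent-dipole fitting, and the dipolarity/inside-head
# screen that separates brain ICs from artifact ICs.

#' Construct a three-shell spherical head model
#'
#' Concentric brain / skull / scalp shells. The series solution is computed
#' in scalp-radius units (radii normalized to 1) for numerical conditioning;
#' the per-order interface coefficients are cached in the object.
#'
#' @param radii_mm shell radii (brain, skull, scalp), strictly increasing.
#' @param conductivities shell conductivities in S/m (brain, skull, scalp);
#'   the default skull:brain ratio is 1:79.
#' @param order Legendre-series truncation order.
#' @return an object of class `head_model`.
#' @export
head_model <- function(radii_mm = c(80, 85, 92),
                       conductivities = c(0.33, 0.0042, 0.33),
                       order = 60) {
  if (any(diff(radii_mm) <= 0)) abort_validation("shell radii must be strictly increasing")
  if (any(conductivities <= 0)) abort_validation("conductivities must be positive")
  hm <- list(radii_mm = radii_mm, conductivities = conductivities, order = order)
  hm$coef <- shell_coefficients(radii_mm, conductivities, order)
  structure(hm, class = "head_model")
}

# Per-order radial coefficient c_n of the scalp-surface potential for a unit
# source coefficient (particular solution rho^-(n+1) inside the brain shell).
# For each n the five interface/boundary conditions (potential and radial
# current continuity at the two inner interfaces, zero outward current at the
# scalp) form a 5x5 linear system in (A1, A2, B2, A3, B3); radii are in
# scalp-radius units.
shell_coefficients <- function(radii_mm, sigma, order) {
  R <- radii_mm[3]
  r1 <- radii_mm[1] / R; r2 <- radii_mm[2] / R; r3 <- 1
  vapply(seq_len(order), function(n) {
    m <- matrix(0, 5, 5)
    b <- numeric(5)
    # unknown order: A1, A2, B2, A3, B3
    m[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
    b[1] <- -r1^(-(n + 1))
    m[2, ] <- c(sigma[1] * n * r1^(n - 1),
                -sigma[2] * n * r1^(n - 1), sigma[2] * (n + 1) * r1^(-(n + 2)), 0, 0)
    b[2] <- sigma[1] * (n + 1) * r1^(-(n + 2))
    m[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    m[4, ] <- c(0, sigma[2] * n * r2^(n - 1), -sigma[2] * (n + 1) * r2^(-(n + 2)),
                -sigma[3] * n * r2^(n - 1), sigma[3] * (n + 1) * r2^(-(n + 2)))
    m[5, ] <- c(0, 0, 0, sigma[3] * n * r3^(n - 1), -sigma[3] * (n + 1) * r3^(-(n + 2)))
    x <- solve(m, b)
    x[4] * r3^n + x[5] * r3^(-(n + 1))   # scalp-surface value A3 + B3
  }, numeric(1))
}

# Legendre P_n(u) and P_n'(u), n = 1..order, for a vector of u in [-1, 1].
# Returns list of two (length(u) x order) matrices. Bonnet recurrences.
legendre_table <- function(u, order) {
  nu <- length(u)
  P <- matrix(0, nu, order + 1)
  P[, 1] <- 1          # P_0
  P[, 2] <- u          # P_1
  if (order >= 2) for (n in 1:(order - 1))
    P[, n + 2] <- ((2 * n + 1) * u * P[, n + 1] - n * P[, n]) / (n + 1)
  dP <- matrix(0, nu, order + 1)
  dP[, 2] <- 1
  if (order >= 2) for (n in 2:order)
    dP[, n + 1] <- n * P[, n] + u * dP[, n]   # P_n' = n P_{n-1} + u P_{n-1}'
  list(P = P[, -1, drop = FALSE], dP = dP[, -1, drop = FALSE])
}

#' Scalp potentials of a current dipole in the three-shell model
#'
#' Closed-form concentric-shell Legendre series, linear in the moment. The
#' potential at electrode direction \eqn{\hat r} from a dipole at position
#' \eqn{b} with moment \eqn{m} is
#' \deqn{V = \frac{1}{4\pi\sigma_1 R^2}\sum_n c_n f^{n-1}
#'   [\, n P_n(u) (m\cdot\hat b) + P_n'(u)\, m\cdot(\hat r - u \hat b)\,]}
#' with eccentricity \eqn{f = |b|/R} and \eqn{u = \hat r\cdot\hat b}.
#'
#' @param position dipole position (mm, head-model frame).
#' @param moment dipole moment vector (source units).
#' @param hm a [head_model()].
#' @param montage electrode `montage`; positions are projected radially onto
#'   the scalp sphere for evaluation.
#' @param order optional override of the series truncation order.
#' @return numeric vector of electrode potentials.
#' @export
dipole_potential <- function(position, moment, hm, montage, order = hm$order) {
  if (sqrt(sum(position^2)) >= hm$radii_mm[1])
    abort_validation("dipole position outside the brain shell (|r| = ",
                     sprintf("%.1f", sqrt(sum(position^2))), " mm)")
  G <- dipole_gain(position, hm, montage, order)
  as.numeric(G %*% moment)
}

#' Electrode gain matrix of a dipole position (linear in the moment)
#'
#' Unlike [dipole_potential()], positions anywhere inside the scalp sphere
#' are accepted: the series is formally derived for sources in the brain
#' shell but is conventionally evaluated beyond it during dipole fitting, so
#' that maps generated by periocular or muscle processes fit best at
#' positions outside the brain and are caught by the inside-brain screen.
#'
#' @inheritParams dipole_potential
#' @return channels x 3 matrix G with potentials = G %*% moment.
#' @export
dipole_gain <- function(position, hm, montage, order = hm$order) {
  R <- hm$radii_mm[3]
  b <- sqrt(sum(position^2))
  if (b >= R)
    abort_validation("dipole position outside the scalp sphere (|r| = ",
                     sprintf("%.1f", b), " mm)")
  cn <- if (order == hm$order) hm$coef
        else shell_coefficients(hm$radii_mm, hm$conductivities, order)
  bhat <- if (b > 1e-9) position / b else c(0, 0, 1)
  E <- montage$positions
  rhat <- E / sqrt(rowSums(E^2))
  u <- pmax(-1, pmin(1, as.numeric(rhat %*% bhat)))
  leg <- legendre_table(u, order)
  f <- b / R
  fpow <- f^(0:(order - 1))                       # f^(n-1); 0^0 = 1
  w <- cn * fpow                                  # per-order weight
  # radial part: sum_n w_n * n * P_n(u) * (m . bhat)
  rad <- as.numeric(leg$P %*% (w * seq_len(order)))
  # tangential part: sum_n w_n * P_n'(u) times m . (rhat - u bhat)
  tang <- as.numeric(leg$dP %*% w)
  scale <- 1 / (4 * pi * hm$conductivities[1] * (R / 1000)^2)  # radii mm -> m
  G <- scale * (outer(rad, bhat) + tang * (rhat - outer(u, bhat)))
  rownames(G) <- montage$channel_names
  G
}

avg_reference <- function(x) x - mean(x)

# residual variance of the least-squares moment fit at a fixed position
rv_at_position <- function(position, map_ar, hm, montage) {
  G <- dipole_gain(position, hm, montage)
  G <- sweep(G, 2, colMeans(G))          # average-reference the gains
  fit <- tryCatch(qr.solve(G, map_ar), error = function(e) NULL)
  if (is.null(fit)) return(list(rv = 1, moment = c(0, 0, 0)))
  res <- map_ar - G %*% fit
  list(rv = sum(res^2) / sum(map_ar^2), moment = as.numeric(fit))
}

#' Fit a single equivalent current dipole to an IC scalp map
#'
#' Minimizes residual map variance over dipole position with the optimal
#' moment solved linearly at each position (simplex search, multi-start from
#' interior points). Maps are average-referenced before fitting since scalp
#' potentials are defined only up to a constant.
#'
#' @param map scalp map (one value per montage channel).
#' @param hm a [head_model()].
#' @param montage electrode `montage`.
#' @param n_starts number of interior starting points.
#' @param seed integer seed controlling the start points.
#' @return a `dipole_fit`: list with `position` (mm), `moment`, `rv`
#'   (residual variance in \[0, 1\]; dipolarity = 1 - rv), `inside_brain`.
#' @export
fit_dipole <- function(map, hm, montage, n_starts = 8, seed = 1) {
  if (length(map) != length(montage$channel_names))
    abort_validation("map length must match montage channel count")
  map_ar <- avg_reference(as.numeric(map))
  if (sum(map_ar^2) == 0) abort_validation("cannot fit a dipole to a constant map")
  rb <- hm$radii_mm[1]
  rs <- hm$radii_mm[3]
  set.seed(seed)
  starts <- matrix(stats::runif(3 * n_starts, -0.6, 0.6) * rb, ncol = 3)
  starts[1, ] <- c(0, 0, 0.5 * rb)               # deterministic central start
  obj <- function(p) {
    if (sum(p^2) >= (0.97 * rs)^2) return(1 + sqrt(sum(p^2)) / rs)  # barrier
    rv_at_position(p, map_ar, hm, montage)$rv
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || o$value < best$value - 1e-12 ||
        (abs(o$value - best$value) <= 1e-12 &&
         sum(o$par^2) < sum(best$par^2))) best <- o
  }
  sol <- rv_at_position(best$par, map_ar, hm, montage)
  structure(list(position = as.numeric(best$par), moment = sol$moment,
                 rv = sol$rv,
                 inside_brain = sqrt(sum(best$par^2)) < hm$radii_mm[1]),
            class = "dipole_fit")
}

#' Screen ICs by dipolarity and inside-brain location
#'
#' Retains ICs whose equivalent-dipole model explains at least
#' `1 - rv_max` of the scalp-map variance (default 85%) and whose dipole
#' lies inside the brain shell.
#'
#' @param fits list of `dipole_fit` objects, one per IC.
#' @param rv_max maximum residual variance (default 0.15).
#' @param require_inside if `TRUE`, exclude dipoles outside the brain shell.
#' @return integer vector of retained IC indices.
#' @export
screen_ics <- function(fits, rv_max = 0.15, require_inside = TRUE) {
  keep <- vapply(fits, function(f)
    f$rv <= rv_max && (f$inside_brain || !require_inside), logical(1))
  which(keep)
}
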