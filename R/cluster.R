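# Across-subject IC clustering in a weighted multi-measure feature space:
# equivalent dipole location (3 dims, weight 10, used raw), scalp map (PCA to
# 7 dims, weight 3), mean log power spectrum (PCA to 5, weight 2), and the
# concatenated Standard/Deviant ERPs (joint PCA to 5, weight 1), k-means with
# k = 20, RMS-distance outlier rejection, and cluster accounting with
# Talairach centroid conversion.

#' One IC's record for across-subject clustering
#'
#' @param subject_id,group subject tags. @param ic IC index within subject.
#' @param map unit-norm scalp map. @param fit a `dipole_fit`.
#' @param spectrum log-power spectrum values (3-50 Hz grid).
#' @param erp_std,erp_dev condition ERPs (0-500 ms, source-resolved,
#'   scalp-projected units, common time base).
#' @return an `ic_record`.
#' @export
ic_record <- function(subject_id, group, ic, map, fit, spectrum, erp_std, erp_dev) {
  structure(list(subject_id = subject_id, group = group, ic = ic, map = map,
                 fit = fit, spectrum = spectrum, erp_std = erp_std,
                 erp_dev = erp_dev),
            class = "ic_record")
}

#' Feature dimensions and weights for preclustering
#' @param dipole,map,spectrum,erp `c(dims, weight)` pairs.
#' @return a `feature_spec`.
#' @export
feature_spec <- function(dipole = c(3, 10), map = c(7, 3),
                         spectrum = c(5, 2), erp = c(5, 1)) {
  for (m in list(dipole, map, spectrum, erp)) {
    if (m[1] < 1) abort_validation("measure dims must be >= 1")
    if (m[2] <= 0) abort_validation("measure weights must be positive")
  }
  structure(list(dipole = dipole, map = map, spectrum = spectrum, erp = erp),
            class = "feature_spec")
}

# z-normalize columns, PCA-reduce to k dims, rescale the block to unit total
# variance, multiply by weight
measure_block <- function(raw, dims, weight, pca = TRUE) {
  Z <- apply(raw, 2, zscore0)
  if (pca) {
    dims <- min(dims, ncol(Z), nrow(Z) - 1)
    pr <- stats::prcomp(Z, center = FALSE)
    Z <- pr$x[, seq_len(dims), drop = FALSE]
  }
  tv <- sum(apply(Z, 2, stats::var))
  if (tv > 0) Z <- Z / sqrt(tv)
  Z * weight
}

#' Build weighted feature vectors from IC records
#'
#' Dipole positions enter raw (3-D, no PCA); all other measures are
#' z-normalized per dimension and PCA-reduced to the spec's dimensions;
#' each measure block is rescaled to unit total variance and multiplied by
#' its weight before concatenation (so a weight scales its squared-distance
#' contribution quadratically).
#'
#' @param records list of [ic_record()]s.
#' @param spec a [feature_spec()].
#' @return numeric matrix, records x total dims (20 under the default spec).
#' @export
build_feature_vectors <- function(records, spec = feature_spec()) {
  n <- length(records)
  need <- max(spec$dipole[1], spec$map[1], spec$spectrum[1], spec$erp[1]) + 1
  if (n < need) abort_validation("need at least ", need, " IC records")
  pos <- t(vapply(records, function(r) r$fit$position, numeric(3)))
  maps <- t(vapply(records, function(r) as.numeric(r$map),
                   numeric(length(records[[1]]$map))))
  specs <- t(vapply(records, function(r) as.numeric(r$spectrum),
                    numeric(length(records[[1]]$spectrum))))
  erps <- t(vapply(records, function(r) c(r$erp_std, r$erp_dev),
                   numeric(length(records[[1]]$erp_std) + length(records[[1]]$erp_dev))))
  F <- cbind(measure_block(pos, spec$dipole[1], spec$dipole[2], pca = FALSE),
             measure_block(maps, spec$map[1], spec$map[2]),
             measure_block(specs, spec$spectrum[1], spec$spectrum[2]),
             measure_block(erps, spec$erp[1], spec$erp[2]))
  rownames(F) <- vapply(records, function(r) paste0(r$subject_id, ":", r$ic), "")
  F
}

#' k-means clustering of IC feature vectors
#'
#' Euclidean k-means, best of `restarts` by within-cluster sum of squares;
#' deterministic under `seed`.
#'
#' @param features records x dims matrix from [build_feature_vectors()].
#' @param k number of clusters (default 20).
#' @param restarts random restarts.
#' @param seed integer seed.
#' @return a `cluster_set`: `assignments` (cluster id per record, NA =
#'   outlier), `centroids`, `k`, `features`.
#' @export
kmeans_cluster <- function(features, k = 20, restarts = 50, seed = 1) {
  if (k > nrow(features)) abort_validation("k must not exceed the number of records")
  set.seed(seed)
  km <- stats::kmeans(features, centers = k, nstart = restarts, iter.max = 200)
  structure(list(assignments = km$cluster, centroids = km$centers, k = k,
                 features = features),
            class = "cluster_set")
}

#' Mark cluster outliers by RMS distance
#'
#' ICs farther than `sd` times their cluster's RMS member-to-centroid
#' distance are marked as outliers (assignment NA); centroids are recomputed
#' once.
#'
#' @param cs a `cluster_set`. @param sd threshold multiplier (default 3).
#' @return the updated `cluster_set`.
#' @export
reject_outliers <- function(cs, sd = 3) {
  asg <- cs$assignments
  for (cl in seq_len(cs$k)) {
    mem <- which(asg == cl)
    if (length(mem) < 2) next
    d <- sqrt(rowSums((cs$features[mem, , drop = FALSE] -
                       matrix(cs$centroids[cl, ], length(mem), ncol(cs$features),
                              byrow = TRUE))^2))
    rms <- sqrt(mean(d^2))
    asg[mem[d > sd * rms]] <- NA
  }
  cent <- cs$centroids
  for (cl in seq_len(cs$k)) {
    mem <- which(asg == cl)
    if (length(mem)) cent[cl, ] <- colMeans(cs$features[mem, , drop = FALSE])
  }
  cs$assignments <- asg
  cs$centroids <- cent
  cs
}

#' Template-space to Talairach conversion (piecewise-linear affine)
#'
#' The standard two-piece linear map (different compression above and below
#' the AC plane); the origin is a fixed point.
#'
#' @param xyz n x 3 matrix or length-3 vector (mm).
#' @return same shape, Talairach coordinates.
#' @export
mni_to_talairach <- function(xyz) {
  one <- is.null(dim(xyz))
  if (one) xyz <- matrix(xyz, 1)
  out <- xyz
  up <- xyz[, 3] >= 0
  out[, 1] <- 0.99 * xyz[, 1]
  out[up, 2] <- 0.9688 * xyz[up, 2] + 0.0460 * xyz[up, 3]
  out[up, 3] <- -0.0485 * xyz[up, 2] + 0.9189 * xyz[up, 3]
  out[!up, 2] <- 0.9688 * xyz[!up, 2] + 0.0420 * xyz[!up, 3]
  out[!up, 3] <- -0.0485 * xyz[!up, 2] + 0.8390 * xyz[!up, 3]
  if (one) out[1, ] else out
}

#' Identify clusters of non-brain origin by rule
#'
#' A cluster is flagged non-brain if the median member residual variance
#' exceeds `rv_max` or the median member dipole eccentricity exceeds the
#' brain radius. With the dipolarity screen upstream this is usually a
#' no-op; it is kept for parity with manual artifact-cluster removal.
#'
#' @param cs a `cluster_set`. @param records the clustered [ic_record()]s.
#' @param hm a [head_model()]. @param rv_max dipolarity threshold.
#' @return integer vector of non-brain cluster ids.
#' @export
flag_artifact_clusters <- function(cs, records, hm, rv_max = 0.15) {
  bad <- integer(0)
  for (cl in seq_len(cs$k)) {
    mem <- which(cs$assignments == cl)
    if (!length(mem)) next
    rvs <- vapply(records[mem], function(r) r$fit$rv, numeric(1))
    ecc <- vapply(records[mem], function(r) sqrt(sum(r$fit$position^2)), numeric(1))
    if (stats::median(rvs) > rv_max || stats::median(ecc) > hm$radii_mm[1])
      bad <- c(bad, cl)
  }
  bad
}

#' Per-cluster accounting: centroid dipoles, Talairach, group counts
#'
#' @param cs a `cluster_set`. @param records the clustered [ic_record()]s.
#' @return data.frame with one row per cluster: centroid position, Talairach
#'   conversion, per-group IC and subject counts, and mean ICs per
#'   contributing subject.
#' @export
cluster_report <- function(cs, records) {
  rows <- lapply(seq_len(cs$k), function(cl) {
    mem <- which(cs$assignments == cl)
    if (!length(mem)) {
      return(data.frame(cluster = cl, x = NA, y = NA, z = NA,
                        tal_x = NA, tal_y = NA, tal_z = NA,
                        n_ic_NCS = 0L, n_subj_NCS = 0L, ics_per_subj_NCS = NA,
                        n_ic_SZ = 0L, n_subj_SZ = 0L, ics_per_subj_SZ = NA))
    }
    pos <- colMeans(t(vapply(records[mem], function(r) r$fit$position, numeric(3))))
    tal <- mni_to_talairach(pos)
    grp <- vapply(records[mem], function(r) r$group, "")
    sid <- vapply(records[mem], function(r) r$subject_id, "")
    cnt <- function(g) {
      nic <- sum(grp == g); nsub <- length(unique(sid[grp == g]))
      c(nic, nsub, if (nsub > 0) nic / nsub else NA)
    }
    a <- cnt("NCS"); b <- cnt("SZ")
    data.frame(cluster = cl, x = pos[1], y = pos[2], z = pos[3],
               tal_x = tal[1], tal_y = tal[2], tal_z = tal[3],
               n_ic_NCS = a[1], n_subj_NCS = a[2], ics_per_subj_NCS = a[3],
               n_ic_SZ = b[1], n_subj_SZ = b[2], ics_per_subj_SZ = b[3])
  })
  do.call(rbind, rows)
}
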