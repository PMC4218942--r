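test_that("feature vectors have the documented 20-dim weighted structure", {
  blobs <- make_blob_records(n_per = 8)
  F <- build_feature_vectors(blobs$records)
  expect_identical(ncol(F), 20L)          # 3 + 7 + 5 + 5
  expect_identical(nrow(F), length(blobs$records))
  # identical records produce identical rows
  recs <- blobs$records
  recs[[2]] <- recs[[1]]
  F2 <- build_feature_vectors(recs)
  expect_equal(F2[1, ], F2[2, ])
  # doubling the dipole weight quadruples its squared-distance term
  F_w <- build_feature_vectors(blobs$records,
                               feature_spec(dipole = c(3, 20)))
  d1 <- sum((F[1, 1:3] - F[2, 1:3])^2)
  d2 <- sum((F_w[1, 1:3] - F_w[2, 1:3])^2)
  expect_equal(d2 / d1, 4, tolerance = 1e-9)
  expect_error(build_feature_vectors(blobs$records[1:3]), "at least")
})

test_that("feature construction is invariant to affine rescaling of raw measures", {
  blobs <- make_blob_records(n_per = 8)
  recs2 <- lapply(blobs$records, function(r) {
    r$spectrum <- 3 * r$spectrum + 17     # per-dimension affine change
    r
  })
  F1 <- build_feature_vectors(blobs$records)
  F2 <- build_feature_vectors(recs2)
  expect_equal(abs(F1[, 11:15]), abs(F2[, 11:15]), tolerance = 1e-9)
})

test_that("k-means recovers planted blobs with purity 1 and is order-invariant", {
  blobs <- make_blob_records(n_per = 10)
  F <- build_feature_vectors(blobs$records)
  cs <- kmeans_cluster(F, k = 3, restarts = 20, seed = 2)
  expect_equal(purity(cs$assignments, blobs$truth), 1)
  expect_error(kmeans_cluster(F, k = nrow(F) + 1), class = "devsource_validation_error")
  cs1 <- kmeans_cluster(F, k = 1, restarts = 5, seed = 1)
  expect_true(all(cs1$assignments == 1))
  # permuting record order permutes but does not change the partition
  perm <- sample(nrow(F))
  csP <- kmeans_cluster(F[perm, ], k = 3, restarts = 20, seed = 2)
  lab1 <- cs$assignments[perm]
  tab <- table(lab1, csP$assignments)
  expect_equal(sum(apply(tab, 1, max)), nrow(F))
})

test_that("outlier rejection marks exactly the planted far point and never hurts", {
  blobs <- make_blob_records(n_per = 10)
  F <- build_feature_vectors(blobs$records)
  cs <- kmeans_cluster(F, k = 3, restarts = 20, seed = 2)
  cs0 <- reject_outliers(cs, sd = 3)
  expect_identical(cs0$assignments, cs$assignments)   # nothing beyond 3 SD
  # plant one far feature point into cluster 1 artificially
  far <- cs
  j <- which(far$assignments == 1)[1]
  far$features[j, ] <- far$features[j, ] + 50
  far2 <- reject_outliers(far, sd = 3)
  expect_true(is.na(far2$assignments[j]))
  expect_identical(which(is.na(far2$assignments)), j)
  # removal does not increase within-cluster RMS distance
  rms <- function(csx) {
    out <- 0
    for (cl in 1:3) {
      mem <- which(csx$assignments == cl)
      d <- csx$features[mem, , drop = FALSE] -
        matrix(csx$centroids[cl, ], length(mem), ncol(csx$features), byrow = TRUE)
      out <- out + sum(d^2)
    }
    out
  }
  expect_lte(rms(far2), rms(far))
})

test_that("cluster report counts ICs and subjects the way the bookkeeping requires", {
  blobs <- make_blob_records(n_per = 6)
  recs <- blobs$records
  # force a known membership: cluster of ICs from subjects A, A, B
  recs[[1]]$subject_id <- "A"; recs[[1]]$group <- "NCS"
  recs[[2]]$subject_id <- "A"; recs[[2]]$group <- "NCS"
  recs[[3]]$subject_id <- "B"; recs[[3]]$group <- "NCS"
  F <- build_feature_vectors(recs)
  cs <- structure(list(assignments = c(1, 1, 1, rep(2, length(recs) - 3)),
                       centroids = matrix(0, 2, ncol(F)), k = 2, features = F),
                  class = "cluster_set")
  rep1 <- cluster_report(cs, recs)
  expect_identical(rep1$n_ic_NCS[1], 3)
  expect_identical(rep1$n_subj_NCS[1], 2)
  expect_equal(rep1$ics_per_subj_NCS[1], 1.5)
  # centroid of a single-member cluster equals that member's position
  cs2 <- structure(list(assignments = c(1, rep(NA, length(recs) - 1)),
                        centroids = matrix(0, 1, ncol(F)), k = 1, features = F),
                   class = "cluster_set")
  rep2 <- cluster_report(cs2, recs)
  expect_equal(unlist(rep2[1, c("x", "y", "z")], use.names = FALSE),
               recs[[1]]$fit$position)
})

test_that("the template-to-Talairach transform fixes the origin and compresses z", {
  expect_equal(mni_to_talairach(c(0, 0, 0)), c(0, 0, 0))
  up <- mni_to_talairach(c(10, 20, 30))
  expect_equal(up[1], 9.9)
  expect_lt(up[3], 30)
  dn <- mni_to_talairach(c(0, 0, -20))
  expect_equal(dn[3], -16.78)
})

test_that("artifact-cluster rule flags high-rv or outside-brain clusters", {
  blobs <- make_blob_records(n_per = 6)
  recs <- blobs$records
  for (i in 1:6) recs[[i]]$fit$rv <- 0.5   # cluster 1 members (first blob)
  F <- build_feature_vectors(recs)
  cs <- kmeans_cluster(F, k = 3, restarts = 10, seed = 4)
  bad <- flag_artifact_clusters(cs, recs, fix_hm)
  cl1 <- cs$assignments[1]
  expect_true(cl1 %in% bad)
  expect_length(bad, 1)
})
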