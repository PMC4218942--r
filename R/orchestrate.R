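# End-to-end pipeline: simulate (or load) -> preprocess -> ICA -> dipole fit
# and screen -> across-subject clustering -> source-resolved deviance ERPs,
# pvaf and peak scoring -> group contrasts and the correlation audit. A
# single master seed fans out to per-stage, per-subject substreams.

#' Pipeline parameters (defaults are the emulated study's printed values)
#'
#' @param thresh_uv amplitude-rejection threshold (microvolts).
#' @param sd_single,sd_all improbability-test thresholds (SD units).
#' @param reject_mode window-rejection combination rule.
#' @param lo_hz,hi_hz band-pass edges (Hz).
#' @param ica_iter ICA iteration cap (2000 emulates the reference schedule;
#'   reduce for test profiles).
#' @param ica_reject_sd,ica_reject_iters ICA sample-rejection schedule.
#' @param rv_max dipolarity screen (maximum residual variance).
#' @param k clusters (capped at the number of retained ICs).
#' @param restarts k-means restarts. @param outlier_sd cluster outlier
#'   threshold. @param dipfit_starts dipole-fit multi-starts.
#' @param peak_polarity `"nominal"` or `"free"` peak search.
#' @return a `run_params` list.
#' @export
run_params <- function(thresh_uv = 150, sd_single = 5, sd_all = 2,
                       reject_mode = "any", lo_hz = 1, hi_hz = 100,
                       ica_iter = 2000, ica_reject_sd = 5,
                       ica_reject_iters = c(4, 7, 10, 13, 16),
                       rv_max = 0.15, k = 20, restarts = 20, outlier_sd = 3,
                       dipfit_starts = 4, peak_polarity = "nominal") {
  as.list(environment())
}

subject_stage <- function(rec, id, group, config, params, seed) {
  pp <- preprocess(rec, params$lo_hz, params$hi_hz, params$thresh_uv,
                   params$sd_single, params$sd_all, params$reject_mode)
  prec <- pp$recording
  dec <- run_ica(prec, max_iter = params$ica_iter,
                 reject_sd = params$ica_reject_sd,
                 reject_iters = params$ica_reject_iters,
                 seed = substream_seed(seed, "ica"))
  mon <- config$montage
  hm <- config$head_model
  nic <- ncol(dec$scalp_maps)
  fits <- lapply(seq_len(nic), function(i)
    fit_dipole(dec$scalp_maps[, i], hm, mon, n_starts = params$dipfit_starts,
               seed = substream_seed(seed, "dipfit", i)))
  retained <- screen_ics(fits, rv_max = params$rv_max)
  spect <- ic_spectrum(dec, prec)
  acts <- ic_activations(dec, prec)
  gains <- apply(abs(dec$scalp_maps), 2, max)
  records <- lapply(retained, function(i) {
    e_std <- epoch_and_average(gains[i] * acts[i, ], prec$fs, prec$events,
                               "standard", prec$retained_mask)
    e_dev <- epoch_and_average(gains[i] * acts[i, ], prec$fs, prec$events,
                               "deviant", prec$retained_mask)
    t0 <- e_std$time_ms >= 0
    ic_record(id, group, i, dec$scalp_maps[, i], fits[[i]],
              spect$spectrum[i, ], e_std$waveform[1, t0], e_dev$waveform[1, t0])
  })
  # artifact-removed channel data: back-projection of screened-in ICs only
  clean <- dec$mixing[, retained, drop = FALSE] %*% acts[retained, , drop = FALSE] +
    dec$channel_means
  rownames(clean) <- prec$channel_names
  e_std <- epoch_and_average(clean, prec$fs, prec$events, "standard", prec$retained_mask)
  e_dev <- epoch_and_average(clean, prec$fs, prec$events, "deviant", prec$retained_mask)
  diff <- deviance_response(e_dev, e_std)
  list(id = id, group = group, decomposition = dec, fits = fits,
       retained = retained, records = records, reject_report = pp$report,
       scalp_deviance = diff,
       acts = acts, fs = prec$fs, events = prec$events,
       retained_mask = prec$retained_mask)
}

#' Run the full source-resolved deviance pipeline on a synthetic cohort
#'
#' @param config a [cohort_config()] (e.g. [test_profile_config()]).
#' @param params a [run_params()].
#' @param out_dir optional directory for persisted artifacts (peak table and
#'   membership TSVs, audit and run-report JSON).
#' @param verbose print stage progress.
#' @return a `run_report` list: per-stage counts, the cluster report, cluster
#'   pvaf table, the peak table, group contrasts, the correlation audit, and
#'   a pvaf-conservation check.
#' @export
run_pipeline <- function(config, params = run_params(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulate: ", config$n_ncs, "+", config$n_sz, " subjects")
  cohort <- generate_cohort(config)

  subjects <- list()
  for (id in names(cohort$recordings)) {
    say("subject ", id)
    grp <- cohort$scores$group[cohort$scores$subject_id == id]
    subjects[[id]] <- subject_stage(cohort$recordings[[id]], id, grp, config,
                                    params,
                                    substream_seed(config$seed, "stage", id))
  }

  records <- do.call(c, lapply(subjects, `[[`, "records"))
  if (length(records) < 2) stop("pipeline aborted at stage cluster: too few retained ICs")
  k_eff <- min(params$k, length(records))
  feats <- build_feature_vectors(records)
  cs <- kmeans_cluster(feats, k = k_eff, restarts = params$restarts,
                       seed = substream_seed(config$seed, "kmeans"))
  cs <- reject_outliers(cs, sd = params$outlier_sd)
  bad <- flag_artifact_clusters(cs, records, config$head_model, params$rv_max)
  creport <- cluster_report(cs, records)

  # grand-average artifact-removed scalp deviance (equal subject weights)
  time_ms <- subjects[[1]]$scalp_deviance$time_ms
  total_ga <- Reduce(`+`, lapply(subjects, function(s) s$scalp_deviance$waveform)) /
    length(subjects)
  rownames(total_ga) <- config$montage$channel_names

  rec_sub <- vapply(records, function(r) r$subject_id, "")
  rec_ic <- vapply(records, function(r) r$ic, numeric(1))
  t0 <- time_ms >= 0

  cluster_ids <- setdiff(sort(unique(stats::na.omit(cs$assignments))), bad)
  peak_rows <- list()
  pvaf_rows <- list()
  union_ga <- matrix(0, nrow(total_ga), ncol(total_ga))
  for (cl in cluster_ids) {
    mem <- which(cs$assignments == cl)
    contrib <- list()
    for (id in names(subjects)) {
      smem <- mem[rec_sub[mem] == id]
      if (!length(smem)) next
      s <- subjects[[id]]
      maps <- s$decomposition$scalp_maps[, rec_ic[smem], drop = FALSE]
      gains <- apply(abs(maps), 2, max)
      wav <- t(vapply(seq_along(smem), function(j) {
        i <- rec_ic[smem[j]]
        e_s <- epoch_and_average(s$acts[i, ], s$fs, s$events, "standard", s$retained_mask)
        e_d <- epoch_and_average(s$acts[i, ], s$fs, s$events, "deviant", s$retained_mask)
        e_d$waveform[1, ] - e_s$waveform[1, ]
      }, numeric(length(time_ms))))
      bp <- backproject(maps, wav)
      contrib[[id]] <- bp$channel_waveforms
      pks <- score_peaks(bp$trace, time_ms, polarity = params$peak_polarity)
      pks$subject <- id; pks$group <- s$group; pks$source <- sprintf("C%02d", cl)
      peak_rows[[length(peak_rows) + 1]] <- pks
    }
    if (!length(contrib)) next
    cl_mean <- Reduce(`+`, contrib) / length(contrib)
    union_ga <- union_ga + Reduce(`+`, contrib) / length(subjects)
    pvaf_rows[[length(pvaf_rows) + 1]] <- data.frame(
      cluster = sprintf("C%02d", cl), n_subjects = length(contrib),
      pvaf = pvaf(cl_mean, total_ga, time_ms, c(0, 500)))
  }

  # residual: ICs retained by the screen but outlying or in artifact clusters
  resid_ga <- total_ga - union_ga
  conservation <- pvaf(union_ga + resid_ga, total_ga, time_ms, c(0, 500))

  for (id in names(subjects)) {
    pks <- fz_reference_measures(subjects[[id]]$scalp_deviance,
                                 polarity = params$peak_polarity)
    pks$subject <- id; pks$group <- subjects[[id]]$group; pks$source <- "Fz"
    peak_rows[[length(peak_rows) + 1]] <- pks
  }
  peak_table <- do.call(rbind, peak_rows)
  names(peak_table)[names(peak_table) == "amplitude"] <- "amplitude"

  contrasts <- group_contrasts(peak_table)
  audit <- tryCatch(
    correlation_audit(peak_table, cohort$scores, group = "SZ"),
    error = function(e) NULL)

  report <- list(
    seed = config$seed,
    params = params,
    n_subjects = length(subjects),
    trials_retained = t(vapply(subjects, function(s)
      c(standard = s$reject_report$retained_standard,
        deviant = s$reject_report$retained_deviant), numeric(2))),
    ics_retained = vapply(subjects, function(s) length(s$retained), numeric(1)),
    k = k_eff, artifact_clusters = bad,
    cluster_report = creport,
    cluster_pvaf = do.call(rbind, pvaf_rows),
    pvaf_conservation = conservation,
    peak_table = peak_table,
    contrasts = contrasts,
    audit = audit,
    scores = cohort$scores,
    truth = cohort$truth,
    assignments = cs$assignments,
    records = records,
    time_ms = time_ms,
    total_deviance_ga = total_ga)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(peak_table, file.path(out_dir, "peak_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(creport, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(contrasts))
      utils::write.table(contrasts, file.path(out_dir, "contrasts.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    summ <- list(seed = config$seed, params = params,
                 ics_retained = report$ics_retained,
                 trials_retained = as.data.frame(report$trials_retained),
                 k = k_eff, artifact_clusters = bad,
                 pvaf = report$cluster_pvaf,
                 pvaf_conservation = conservation,
                 critical_r2 = if (!is.null(audit)) audit$critical_r2 else NULL,
                 strata = if (!is.null(audit)) audit$strata else NULL)
    jsonlite::write_json(summ, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = 8, force = TRUE,
                         dataframe = "rows")
  }
  report
}
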