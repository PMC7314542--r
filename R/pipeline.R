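# End-to-end orchestration: subject-level pipeline (normalize -> spectra ->
# individualized detection -> coupling) and cohort-level inference, with a
# round-trippable configuration and seed-fanned determinism.

#' Pipeline configuration
#'
#' All tunables with their standing defaults: 15-s/1-s spectral windows,
#' IRASA factors 1.1-1.9 (step 0.05), SO band < 2 Hz, spindle band
#' 10-18 Hz, SO duration 0.8-2 s, spindle duration 0.5-3 s, 75th-percentile
#' thresholds, 200-ms envelope smoothing, +-2.5-s epochs, 22.5-degree
#' preferred-phase radius, 500 x 100 bootstrap, 1000 permutations, coupling
#' restricted to NREM3.  `individual_peaks = FALSE` switches the spindle
#' detector to the fixed `fixed_band` (11-15 Hz) control analysis.
#'
#' @param ... overrides for any listed field.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    spindle_band = c(10, 18), so_band_max = 2, theta_band = c(4, 8),
    so_dur = c(0.8, 2), spindle_dur = c(0.5, 3),
    percentile = 75, smooth_sec = 0.2,
    epoch_half_width = 2.5, preferred_radius_deg = 22.5,
    bootstrap_n_draw = 500, bootstrap_n_boot = 100,
    n_perm = 1000, cluster_alpha = 0.05, alpha = 0.05,
    coupling_stage = "N3", detection_stages = c("N2", "N3"),
    spectral_max_sec = Inf,
    individual_peaks = TRUE, fixed_band = c(11, 15),
    default_spindle_freq = 13
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$percentile > 0, cfg$percentile < 100,
            cfg$spindle_band[1] < cfg$spindle_band[2],
            cfg$so_dur[1] < cfg$so_dur[2],
            cfg$spindle_dur[1] < cfg$spindle_dur[2],
            cfg$bootstrap_n_boot >= 0, cfg$n_perm >= 1,
            cfg$coupling_stage %in% SLEEP_STAGES)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$spectral_max_sec <- if (is.null(raw$spectral_max_sec) ||
                              identical(raw$spectral_max_sec, ".inf") ||
                              is.character(raw$spectral_max_sec)) Inf
                          else raw$spectral_max_sec
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the subject-level pipeline
#'
#' Per channel: z-normalization on artifact-free NREM samples, mixed + IRASA
#' spectra, individual SO/spindle peak parameterization, individualized
#' event detection (thresholds computed on the pooled NREM2+NREM3 mask),
#' spindle density, SO-spindle co-occurrence, and event-locked coupling on
#' the coupling stage (NREM3 by default).  Deterministic given `seed`.
#'
#' @param rec a [psg_recording()] with hypnogram.
#' @param config a [pipeline_config()].
#' @param seed integer seed (fanned out to the stochastic stages).
#' @param channels channel indices/labels; default all.
#' @return object of class `subject_result`: tidy `summary` data.frame (one
#'   row per channel), `events` table, per-channel `phases`, `spectra`,
#'   optional `bootstrap`, and `provenance`.
#' @export
run_subject <- function(rec, config = pipeline_config(), seed = 1L,
                        channels = NULL) {
  chs <- if (is.null(channels)) seq_len(nrow(rec$signal)) else
    vapply(channels, resolve_channel, 0L, rec = rec)
  hyp <- unclass(rec$hypnogram)
  has_stage <- function(st) any(hyp == st)
  det_stages <- config$detection_stages

  masks <- lapply(chs, function(ch)
    stage_sample_mask(rec, det_stages, exclude_artifacts = TRUE, channel = ch))
  mask_mat <- do.call(rbind, masks)
  full_mask <- matrix(FALSE, nrow(rec$signal), n_samples(rec))
  full_mask[chs, ] <- mask_mat
  for (ch in setdiff(seq_len(nrow(rec$signal)), chs)) full_mask[ch, ] <- TRUE
  recz <- znormalize(rec, full_mask)

  summary_rows <- list(); events_rows <- list()
  phases_all <- list(); spectra <- list(); boots <- list()
  for (k in seq_along(chs)) {
    ch <- chs[k]; lab <- rec$channel_labels[ch]
    mask <- masks[[k]]
    dec <- irasa(recz, mask, channels = ch, max_sec = config$spectral_max_sec)
    so_peak <- find_band_peak(dec, "so", 1L)
    sp_peak <- find_band_peak(dec, c(config$spindle_band[1],
                                     config$spindle_band[2]), 1L)
    center <- if (!config$individual_peaks) mean(config$fixed_band)
      else if (!is.null(sp_peak)) sp_peak$freq
      else config$default_spindle_freq
    so_ev <- detect_so(recz, ch, mask, dur_range = config$so_dur,
                       percentile = config$percentile)
    sp_ev <- detect_spindles(recz, ch, mask, peak_freq = center,
                             dur_range = config$spindle_dur,
                             percentile = config$percentile,
                             smooth_sec = config$smooth_sec)
    stage_at <- function(t) hyp[pmin(floor(t / EPOCH_SEC) + 1L, length(hyp))]
    so_ev$stage <- if (nrow(so_ev)) stage_at(so_ev$trough_time) else character(0)
    sp_ev$stage <- if (nrow(sp_ev)) stage_at(sp_ev$peak_time) else character(0)
    cst <- config$coupling_stage
    density <- if (has_stage(cst)) {
      spindle_density(sp_ev$peak_time, rec$hypnogram, cst)
    } else NA_real_
    so_n3 <- so_ev[so_ev$stage == cst, , drop = FALSE]
    sp_n3 <- sp_ev[sp_ev$stage == cst, , drop = FALSE]
    coocc <- cooccurrence_rate(so_n3, sp_n3)

    status <- "ok"; phases <- numeric(0)
    pp <- strength <- pct <- NA_real_
    if (!has_stage(cst)) {
      status <- "no-coupling-stage"
    } else if (nrow(sp_n3) == 0L) {
      status <- "no-events"
    } else {
      ep <- suppressWarnings(
        extract_epochs(recz, sp_n3$peak_time, ch,
                       half_width = config$epoch_half_width, normalize = TRUE))
      if (nrow(ep$data) == 0L) {
        status <- "no-events"
      } else {
        phases <- so_phase_at_spindle_peak(ep)
        pp <- preferred_phase(phases)
        strength <- coupling_strength(phases)
        pct <- if (is.na(pp)) NA_real_ else
          pct_in_preferred(phases, pp, config$preferred_radius_deg * pi / 180)
        if (config$bootstrap_n_boot > 0) {
          boots[[lab]] <- bootstrap_coupling(
            phases, config$bootstrap_n_draw, config$bootstrap_n_boot,
            seed = derive_seed(seed, paste0("boot-", lab)))
        }
      }
    }
    summary_rows[[k]] <- data.frame(
      channel = lab, stage = cst,
      spindle_peak_freq = if (!is.null(sp_peak)) sp_peak$freq else NA_real_,
      spindle_peak_amp = if (!is.null(sp_peak)) sp_peak$amp else NA_real_,
      so_peak_freq = if (!is.null(so_peak)) so_peak$freq else NA_real_,
      center_freq = center,
      n_so = nrow(so_ev), n_spindles = nrow(sp_ev),
      n_so_stage = nrow(so_n3), n_spindles_stage = nrow(sp_n3),
      spindle_density = density, cooccurrence_pct = coocc,
      n_coupling_events = length(phases),
      preferred_phase = pp, coupling_strength = strength,
      pct_in_preferred = pct, status = status)
    if (nrow(so_ev)) {
      events_rows[[length(events_rows) + 1L]] <- data.frame(
        channel = lab, type = "so", start = so_ev$start,
        anchor = so_ev$trough_time, end = so_ev$end,
        duration = so_ev$duration, amplitude = so_ev$amplitude,
        stage = so_ev$stage)
    }
    if (nrow(sp_ev)) {
      events_rows[[length(events_rows) + 1L]] <- data.frame(
        channel = lab, type = "spindle", start = sp_ev$start,
        anchor = sp_ev$peak_time, end = sp_ev$end,
        duration = sp_ev$duration, amplitude = sp_ev$peak_amplitude,
        stage = sp_ev$stage)
    }
    phases_all[[lab]] <- phases
    spectra[[lab]] <- dec
  }
  structure(list(
    summary = do.call(rbind, summary_rows),
    events = if (length(events_rows)) do.call(rbind, events_rows) else NULL,
    phases = phases_all, spectra = spectra, bootstrap = boots,
    provenance = list(config_hash = config_hash(config), seed = seed,
                      package_version = as.character(utils::packageVersion("socoupling")))),
    class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat("subject_result (seed", x$provenance$seed, ")\n")
  print(x$summary[, c("channel", "center_freq", "n_so", "n_spindles",
                      "cooccurrence_pct", "n_coupling_events",
                      "coupling_strength", "status")])
  invisible(x)
}

#' Write a subject result to disk
#'
#' Deterministic tab-separated tables (`summary.tsv`, `events.tsv`) plus a
#' JSON provenance record; identical inputs and seed produce byte-identical
#' files.
#'
#' @param res a `subject_result`.
#' @param dir output directory (created if absent).
#' @export
write_subject_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    df
  }
  utils::write.table(fmt(res$summary), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$events)) {
    utils::write.table(fmt(res$events), file.path(dir, "events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run the cohort-level analysis
#'
#' Computes per-subject t2 - t1 changes in coupling strength per channel,
#' relates them to the change in delayed recall by a cluster-corrected
#' Spearman correlation over the channel montage, partials out configurable
#' confounds (spindle-density change by default), and compares the
#' coupling-memory correlation against the density-memory correlation with
#' the percentile bootstrap for dependent correlations.
#'
#' @param results_t1,results_t2 named lists of `subject_result`s (same
#'   subject ids in both).
#' @param behavior data.frame with `subject`, `timepoint` ("t1"/"t2"),
#'   `delayed` (and optionally `immediate`) recall percentages.
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return list with `clusters` (a `cluster_result`), `rho` per channel,
#'   `delta_strength`/`delta_recall`/`delta_density` tables, `partial_rho`
#'   (density-partialed, at the peak channel) and `corr_comparison`.
#' @export
run_cohort <- function(results_t1, results_t2, behavior,
                       config = pipeline_config(), seed = 1L) {
  ids1 <- names(results_t1); ids2 <- names(results_t2)
  if (is.null(ids1)) ids1 <- as.character(seq_along(results_t1))
  if (is.null(ids2)) ids2 <- as.character(seq_along(results_t2))
  unmatched <- c(setdiff(ids1, ids2), setdiff(ids2, ids1))
  if (length(unmatched)) {
    stop("unmatched subject id(s): ", paste(unique(unmatched), collapse = ", "))
  }
  subjects <- ids1
  channels <- results_t1[[1]]$summary$channel
  pull <- function(res_list, col) {
    t(vapply(res_list[subjects], function(r) {
      v <- r$summary[[col]][match(channels, r$summary$channel)]
      as.numeric(v)
    }, numeric(length(channels))))
  }
  s1 <- pull(results_t1, "coupling_strength")
  s2 <- pull(results_t2, "coupling_strength")
  d1 <- pull(results_t1, "spindle_density")
  d2 <- pull(results_t2, "spindle_density")
  delta_strength <- s2 - s1
  delta_density <- d2 - d1
  colnames(delta_strength) <- colnames(delta_density) <- channels

  beh <- behavior
  beh$subject <- as.character(beh$subject)
  rec_of <- function(tp) beh$delayed[beh$timepoint == tp][
    match(subjects, beh$subject[beh$timepoint == tp])]
  delta_recall <- rec_of("t2") - rec_of("t1")
  if (anyNA(delta_recall)) stop("behavior table misses subjects: ",
                                paste(subjects[is.na(delta_recall)], collapse = ", "))

  adj <- channel_adjacency(channels)
  clusters <- cluster_permutation_corr(delta_strength, delta_recall, adj,
                                       n_perm = config$n_perm,
                                       cluster_alpha = config$cluster_alpha,
                                       alpha = config$alpha,
                                       seed = derive_seed(seed, "cohort-cluster"))
  rho <- clusters$rho
  names(rho) <- channels
  peak_ch <- which.max(abs(rho))
  partial_rho <- partial_spearman(delta_strength[, peak_ch], delta_recall,
                                  delta_density[, peak_ch])
  comparison <- if (length(subjects) >= 10) {
    bootstrap_compare_dependent_corrs(
      delta_strength[, peak_ch], delta_recall, delta_density[, peak_ch],
      n_boot = 1000, seed = derive_seed(seed, "cohort-bootcmp"))
  } else NULL   # percentile bootstrap unstable below ~10 subjects
  list(clusters = clusters, rho = rho, peak_channel = channels[peak_ch],
       partial_rho = partial_rho, corr_comparison = comparison,
       delta_strength = delta_strength, delta_recall = delta_recall,
       delta_density = delta_density, subjects = subjects)
}
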