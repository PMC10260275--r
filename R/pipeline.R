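# One-night analysis pipeline: preprocessing, NREM spindle and SO
# detection with coupling, REM spectral summary, and the subject-level
# summary row with lateralization indices.

#' Analyze one subject night
#'
#' Runs the full oscillatory pipeline on a recording: broadband zero-phase
#' filtering and linked-mastoid re-referencing; per channel, spindle-band
#' filtering, channel-wise thresholds, spindle detection and density over
#' included NREM (N2 + N3 pooled) minutes; SO detection, SO-band Hilbert
#' phase and SO-spindle pairing; REM band powers and standardized theta
#' for the frontal pair; and the three right-vs-left lateralization
#' indices (F4 vs F3): spindle density, mean coupling distance, and
#' standardized theta.
#'
#' @param recording a [psg_recording()] (raw; preprocessing is applied
#'   here).
#' @param hyp a [hypnogram()].
#' @param artifacts an [artifact_set()].
#' @param cfg configuration, see [default_config()].
#' @param channels EEG channels to analyze (any subset of F3, F4, C3, C4;
#'   theta/REM analysis runs only when both frontal channels are present).
#' @param subject identifier stored in the outputs.
#' @param guard_eps denominator guard for the lateralization indices.
#' @return list of class `night_analysis`: `summary` (one-row data.frame),
#'   `spindles`, `sos`, `pairs`, `coupling` (per-channel summaries),
#'   `band_power`, `nrem_minutes`.
#' @export
analyze_night <- function(recording, hyp, artifacts = artifact_set(),
                          cfg = default_config(),
                          channels = c("F3", "F4", "C3", "C4"),
                          subject = "s01", guard_eps = 1e-6) {
  pre <- preprocess_recording(recording, cfg)
  rate <- pre$rate
  spl <- list(); sol <- list(); prl <- list(); cpl <- list()
  dens <- setNames(rep(NA_real_, length(channels)), channels)
  dist <- setNames(rep(NA_real_, length(channels)), channels)
  nrem_min <- NA_real_
  for (ch in channels) {
    mask <- build_epoch_mask(hyp, artifacts, c("N2", "N3"), cfg, channel = ch)
    minutes <- included_minutes(mask, cfg$density$artifact_corrected)
    nrem_min <- minutes
    x <- pre$data[, channel_index(pre, ch)]
    filt <- spindle_band_filter(x, rate, cfg$bands$spindle,
                                cfg$filter$spindle_order_256)
    thr <- compute_thresholds(filt, mask, rate, cfg, channel = ch)
    sp <- detect_spindles(filt, thr, mask, rate, cfg)
    sos <- detect_sos(x, mask, rate, cfg, channel = ch)
    ph <- so_phase(x, rate, cfg)
    pr <- pair_so_spindles(sos, sp, ph, rate)
    cs <- coupling_summary(pr, channel = ch)
    dens[ch] <- if (minutes > 0) spindle_density(sp, minutes) else NA_real_
    dist[ch] <- cs$mean_distance_rad
    spl[[ch]] <- sp; sol[[ch]] <- sos; prl[[ch]] <- pr; cpl[[ch]] <- cs
  }
  theta <- list(theta_z_F3 = NA_real_, theta_z_F4 = NA_real_,
                rem_theta = NA_real_)
  band_power <- NULL
  if (all(c("F3", "F4") %in% channels)) {
    mask_rem <- build_epoch_mask(hyp, artifacts, "REM", cfg)
    if (any(mask_rem$included)) {
      band_power <- rem_band_power(pre, mask_rem, cfg)
      theta <- standardize_theta(band_power)[c("theta_z_F3", "theta_z_F4",
                                               "rem_theta")]
    }
  }
  frontal <- c("F3", "F4") %in% channels
  central <- c("C3", "C4") %in% channels
  pickv <- function(v, nm) if (nm %in% names(v)) v[[nm]] else NA_real_
  summary <- data.frame(
    subject = subject,
    nrem_minutes = nrem_min,
    density_F3 = pickv(dens, "F3"),
    density_F4 = pickv(dens, "F4"),
    density_frontal = if (all(frontal)) mean(dens[c("F3", "F4")]) else NA_real_,
    density_central = if (all(central)) mean(dens[c("C3", "C4")]) else NA_real_,
    coupling_frontal = if (all(frontal)) mean(dist[c("F3", "F4")]) else NA_real_,
    coupling_central = if (all(central)) mean(dist[c("C3", "C4")]) else NA_real_,
    theta_z_F3 = theta$theta_z_F3, theta_z_F4 = theta$theta_z_F4,
    rem_theta = theta$rem_theta,
    spindle_lat = if (all(frontal))
      lateralization_index(dens[["F4"]], dens[["F3"]], guard_eps) else NA_real_,
    coupling_lat = if (all(frontal))
      lateralization_index(dist[["F4"]], dist[["F3"]], guard_eps) else NA_real_,
    theta_lat = lateralization_index(theta$theta_z_F4, theta$theta_z_F3,
                                     guard_eps),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 spindles = do.call(rbind, c(spl, list(make.row.names = FALSE))),
                 sos = do.call(rbind, c(sol, list(make.row.names = FALSE))),
                 pairs = do.call(rbind, c(prl, list(make.row.names = FALSE))),
                 coupling = do.call(rbind, c(cpl, list(make.row.names = FALSE))),
                 band_power = band_power, nrem_minutes = nrem_min),
            class = "night_analysis")
}

#' Match detected events to injected ground truth
#'
#' A detected event and a true event match when the true peak lies inside
#' the detected span (or within `slack_s` of it). Greedy one-to-one
#' matching in time order.
#'
#' @param detected data.frame with `start_s`, `end_s` (one channel).
#' @param truth data.frame with `peak_s` (same channel).
#' @param slack_s tolerance around the detected span, seconds.
#' @return list: `recall`, `precision`, `n_detected`, `n_true`, `n_matched`.
#' @export
match_events <- function(detected, truth, slack_s = 0.2) {
  n_d <- nrow(detected); n_t <- nrow(truth)
  if (n_t == 0L || n_d == 0L)
    return(list(recall = if (n_t) 0 else NA_real_,
                precision = if (n_d) 0 else NA_real_,
                n_detected = n_d, n_true = n_t, n_matched = 0L))
  used <- logical(n_d)
  matched <- 0L
  for (i in order(truth$peak_s)) {
    pk <- truth$peak_s[i]
    hit <- which(!used & detected$start_s - slack_s <= pk &
                   pk < detected$end_s + slack_s)
    if (length(hit)) { used[hit[1]] <- TRUE; matched <- matched + 1L }
  }
  list(recall = matched / n_t, precision = matched / n_d,
       n_detected = n_d, n_true = n_t, n_matched = matched)
}
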