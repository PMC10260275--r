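# Preprocessing: broadband zero-phase filtering, linked-mastoid
# re-referencing, 30-s epoching and artifact-based epoch exclusion.

#' Re-reference analysis channels to the linked mastoids
#'
#' Every non-mastoid channel x is replaced by x - (A1 + A2)/2. Mastoid
#' channels themselves are left untouched (they carry no information after
#' re-referencing and are ignored downstream).
#'
#' @param recording a [psg_recording()] containing A1 and A2.
#' @return re-referenced [psg_recording()].
#' @export
rereference_mastoids <- function(recording) {
  i1 <- channel_index(recording, "A1")
  i2 <- channel_index(recording, "A2")
  ref <- (recording$data[, i1] + recording$data[, i2]) / 2
  out <- recording
  for (j in seq_along(recording$channel_labels)) {
    if (j == i1 || j == i2) next
    out$data[, j] <- recording$data[, j] - ref
  }
  out
}

#' Broadband-filter and re-reference a recording
#'
#' Applies the 0.2-35 Hz zero-phase FIR band-pass (cut at -6 dB half a
#' transition width outside the passband) to every channel, then
#' re-references to the linked mastoids.
#'
#' @param recording a [psg_recording()].
#' @param cfg configuration, see [default_config()].
#' @param channels channels to filter (default all).
#' @return preprocessed [psg_recording()].
#' @export
preprocess_recording <- function(recording, cfg = default_config(),
                                 channels = recording$channel_labels) {
  bb <- cfg$bands$broadband
  tw <- cfg$filter$broadband_transition
  out <- recording
  h <- design_bandpass(recording$rate, bb[1] - tw / 2, bb[2] + tw / 2,
                       transition = tw)
  for (lab in channels) {
    j <- channel_index(recording, lab)
    out$data[, j] <- apply_fir_zero_phase(recording$data[, j], h)
  }
  rereference_mastoids(out)
}

#' Build the epoch inclusion mask
#'
#' An epoch is included iff its stage belongs to `stages_wanted` and its
#' summed artifact overlap does not exceed the cutoff (8 s by default;
#' epochs with *more* than the cutoff are excluded). For included epochs the
#' overlapping artifact sub-intervals are retained so events inside them can
#' be discarded. Channel-scoped artifact rows apply only when `channel`
#' matches (or is `NULL`, meaning build a channel-agnostic mask from
#' all-channel artifacts only plus rows scoped to nothing).
#'
#' @param hyp a [hypnogram()].
#' @param artifacts an [artifact_set()].
#' @param stages_wanted stages to include, e.g. `c("N2","N3")`.
#' @param cfg configuration (epoch length, cutoff, sum/single rule).
#' @param channel channel label the mask is built for (`NA`-scoped artifact
#'   rows always apply).
#' @param impedance_fail optional logical vector (one per epoch): epochs
#'   flagged `TRUE` are excluded regardless of artifacts (models the
#'   electrode-impedance rule; impedance is hardware metadata not present
#'   in EDF, so the default is all-pass).
#' @return data.frame of class `epoch_mask` with columns `epoch`, `start_s`,
#'   `end_s`, `stage`, `included`, `artifact_s`, and an `intervals`
#'   attribute (per-epoch list of clipped artifact intervals).
#' @export
build_epoch_mask <- function(hyp, artifacts, stages_wanted,
                             cfg = default_config(), channel = NULL,
                             impedance_fail = NULL) {
  ne <- length(hyp$stages)
  el <- hyp$epoch_s
  cutoff <- cfg$epoch$artifact_cutoff_s
  rule <- cfg$epoch$artifact_rule
  keep <- is.na(artifacts$channel)
  if (!is.null(channel))
    keep <- keep | normalize_label(artifacts$channel) == normalize_label(channel)
  arts <- merge_intervals(artifacts$start_s[keep], artifacts$end_s[keep])

  starts <- (seq_len(ne) - 1) * el
  ends <- starts + el
  art_s <- numeric(ne)
  art_max <- numeric(ne)
  intervals <- vector("list", ne)
  if (nrow(arts)) {
    for (i in seq_len(ne)) {
      lo <- pmax(arts[, 1], starts[i]); hi <- pmin(arts[, 2], ends[i])
      ok <- hi > lo
      if (any(ok)) {
        intervals[[i]] <- cbind(lo[ok], hi[ok], deparse.level = 0)
        art_s[i] <- sum(hi[ok] - lo[ok])
        art_max[i] <- max(hi[ok] - lo[ok])
      } else intervals[[i]] <- matrix(numeric(0), ncol = 2)
    }
  } else intervals <- rep(list(matrix(numeric(0), ncol = 2)), ne)

  art_measure <- if (identical(rule, "single")) art_max else art_s
  included <- hyp$stages %in% stages_wanted & art_measure <= cutoff
  if (!is.null(impedance_fail)) included <- included & !impedance_fail
  out <- data.frame(epoch = seq_len(ne), start_s = starts, end_s = ends,
                    stage = hyp$stages, included = included,
                    artifact_s = art_s, stringsAsFactors = FALSE)
  attr(out, "intervals") <- intervals
  attr(out, "epoch_s") <- el
  class(out) <- c("epoch_mask", "data.frame")
  out
}

#' Included sleep time in minutes
#'
#' 0.5 min per included 30-s epoch. With `artifact_corrected = TRUE` the
#' sub-epoch artifact time inside included epochs is subtracted from the
#' denominator (off by default: events inside artifact segments are
#' discarded instead of correcting the time base).
#'
#' @param mask an `epoch_mask` from [build_epoch_mask()].
#' @param artifact_corrected subtract within-epoch artifact time.
#' @return minutes (numeric scalar).
#' @export
included_minutes <- function(mask, artifact_corrected = FALSE) {
  el <- attr(mask, "epoch_s")
  secs <- sum(mask$included) * el
  if (artifact_corrected) secs <- secs - sum(mask$artifact_s[mask$included])
  secs / 60
}

#' Per-sample inclusion mask
#'
#' Expands an epoch mask to sample resolution: `TRUE` for samples inside
#' included epochs and (optionally) outside artifact sub-intervals. Samples
#' beyond the hypnogram's span are excluded.
#'
#' @param mask an `epoch_mask`.
#' @param rate sampling rate, Hz.
#' @param n_samples recording length in samples.
#' @param exclude_artifacts drop artifact sub-intervals inside included
#'   epochs.
#' @return logical vector of length `n_samples`.
#' @export
sample_inclusion <- function(mask, rate, n_samples, exclude_artifacts = TRUE) {
  inc <- logical(n_samples)
  ints <- attr(mask, "intervals")
  for (i in which(mask$included)) {
    a <- min(n_samples, floor(mask$start_s[i] * rate) + 1L)
    b <- min(n_samples, ceiling(mask$end_s[i] * rate))
    if (b < a) next
    inc[a:b] <- TRUE
    if (exclude_artifacts && nrow(ints[[i]])) {
      for (k in seq_len(nrow(ints[[i]]))) {
        u <- max(1L, floor(ints[[i]][k, 1] * rate) + 1L)
        v <- min(n_samples, ceiling(ints[[i]][k, 2] * rate))
        if (v >= u) inc[u:v] <- FALSE
      }
    }
  }
  inc
}
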