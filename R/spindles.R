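# Fast-spindle detection with channel-wise amplitude thresholds, in the
# lineage of mean-amplitude threshold detectors: the 13-16 Hz band-passed
# trace is rectified; the detection thresholds are multiples (5x upper,
# 2x lower) of its mean over artifact-free NREM sleep.

#' Band-pass a signal into the fast-spindle band
#'
#' Zero-phase Hamming-windowed sinc FIR, 13-16 Hz. The filter order is 2816
#' at 256 Hz and scales proportionally with the sampling rate (rounded to
#' even) so the impulse-response duration in seconds is rate-invariant.
#'
#' @param x signal (microvolts).
#' @param rate sampling rate, Hz.
#' @param band passband edges, Hz.
#' @param order_256 FIR order at 256 Hz.
#' @return filtered signal, same length.
#' @export
spindle_band_filter <- function(x, rate, band = c(13, 16), order_256 = 2816) {
  order <- round(order_256 * rate / 256)
  order <- as.integer(order) + as.integer(order) %% 2L
  if (length(x) < 3L * (order + 1L))
    stop(sprintf("signal too short for spindle filter: need >= %d samples, got %d",
                 3L * (order + 1L), length(x)), call. = FALSE)
  h <- design_bandpass(rate, band[1], band[2], order = order)
  apply_fir_zero_phase(x, h)
}

#' Channel-wise spindle detection thresholds
#'
#' The channel's mean amplitude is the mean of the rectified band-passed
#' signal over artifact-free samples of included NREM epochs; the upper
#' (peak) threshold is 5x that mean and the lower (extent) threshold 2x.
#'
#' @param filtered spindle-band filtered signal.
#' @param mask `epoch_mask` restricted to the NREM stages.
#' @param rate sampling rate, Hz.
#' @param cfg configuration (threshold multipliers).
#' @param channel label stored with the thresholds.
#' @return list of class `channel_thresholds`: `channel`, `mean_amp_uv`,
#'   `upper`, `lower`.
#' @export
compute_thresholds <- function(filtered, mask, rate, cfg = default_config(),
                               channel = NA_character_) {
  inc <- sample_inclusion(mask, rate, length(filtered), exclude_artifacts = TRUE)
  if (!any(inc))
    stop("cannot estimate spindle thresholds: no included NREM samples",
         call. = FALSE)
  amp <- if (identical(cfg$spindle$amplitude, "envelope"))
    Mod(hilbert_analytic(filtered)) else abs(filtered)
  m <- mean(amp[inc])
  structure(list(channel = channel, mean_amp_uv = m,
                 upper = cfg$spindle$upper_mult * m,
                 lower = cfg$spindle$lower_mult * m),
            class = "channel_thresholds")
}

#' Detect fast spindles in a filtered channel
#'
#' On the rectified band-passed trace: (1) above-lower-threshold runs are
#' found; (2) runs separated by a sub-lower gap shorter than the minimum
#' inter-spindle gap (78.1 ms, about one 13 Hz period) are bridged into one
#' candidate, so the rectified trace's twice-per-cycle zero dips do not
#' fragment a burst and close-following bursts are absorbed into the
#' earlier event; (3) a candidate becomes a spindle if its rectified
#' maximum exceeds the upper threshold (the peak; first sample on plateau
#' ties) and the trace stays above the lower threshold (gap-bridged) for at
#' least the flank duration (250 ms) on each side of the peak; (4) events
#' longer than 3 s or with peak amplitude above 200 uV are rejected; (5)
#' events touching excluded epochs or artifact segments are dropped.
#'
#' @param filtered spindle-band filtered signal (microvolts).
#' @param thresholds `channel_thresholds` for the same channel.
#' @param mask NREM `epoch_mask`.
#' @param rate sampling rate, Hz.
#' @param cfg configuration (durations, cap, gap).
#' @return data.frame of events, sorted by start time and non-overlapping:
#'   `channel`, `start_s`, `end_s`, `peak_s`, `amplitude_uv`, `duration_s`.
#' @export
detect_spindles <- function(filtered, thresholds, mask, rate,
                            cfg = default_config()) {
  sp <- cfg$spindle
  amp <- if (identical(sp$amplitude, "envelope"))
    Mod(hilbert_analytic(filtered)) else abs(filtered)
  n <- length(amp)
  empty <- data.frame(channel = character(0), start_s = numeric(0),
                      end_s = numeric(0), peak_s = numeric(0),
                      amplitude_uv = numeric(0), duration_s = numeric(0),
                      stringsAsFactors = FALSE)
  above <- amp >= thresholds$lower
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_s <- starts[r$values]
  seg_e <- ends[r$values]
  if (!length(seg_s)) return(empty)

  # bridge sub-lower gaps shorter than the minimum inter-spindle gap
  gap_min <- sp$gap_s * rate
  if (length(seg_s) > 1L) {
    gaps <- seg_s[-1L] - seg_e[-length(seg_e)] - 1L
    new_event <- c(TRUE, gaps >= gap_min)
    grp <- cumsum(new_event)
    seg_s <- tapply(seg_s, grp, min)
    seg_e <- tapply(seg_e, grp, max)
  }

  inc <- sample_inclusion(mask, rate, n, exclude_artifacts = TRUE)
  out <- vector("list", length(seg_s))
  for (k in seq_along(seg_s)) {
    a <- seg_s[k]; b <- seg_e[k]
    pk <- a - 1L + which.max(amp[a:b])        # first sample on plateau ties
    peak_amp <- amp[pk]
    if (peak_amp < thresholds$upper) next
    if ((pk - a) < sp$flank_s * rate) next    # 250 ms above lower before peak
    if ((b - pk) < sp$flank_s * rate) next    # ... and after
    dur <- (b - a + 1L) / rate
    if (dur < sp$min_dur_s || dur > sp$max_dur_s) next
    if (peak_amp > sp$max_amp_uv) next
    if (!all(inc[a:b])) next                  # artifact / excluded-epoch overlap
    out[[k]] <- data.frame(channel = thresholds$channel,
                           start_s = (a - 1L) / rate, end_s = b / rate,
                           peak_s = (pk - 1L) / rate,
                           amplitude_uv = peak_amp, duration_s = dur,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  ev <- do.call(rbind, out)
  ev[order(ev$start_s), , drop = FALSE]
}

#' Spindle density in events per minute
#'
#' @param events spindle event data.frame (or an event count).
#' @param minutes denominator, from [included_minutes()]; must be > 0.
#' @return events/minute.
#' @export
spindle_density <- function(events, minutes) {
  if (!is.numeric(minutes) || minutes <= 0)
    stop("spindle density undefined: included time must be > 0 minutes",
         call. = FALSE)
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / minutes
}
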