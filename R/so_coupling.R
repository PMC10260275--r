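# Slow-oscillation detection by zero-crossing cycle geometry, and
# SO-spindle coupling: Hilbert instantaneous phase of the SO band read at
# the spindle amplitude peak, with the positive SO peak defining phase 0.

#' Detect slow oscillations
#'
#' Two passes over the 3.5 Hz low-pass filtered trace. (1) Candidates:
#' every interval between consecutive positive-to-negative zero crossings
#' with duration 0.8-5 s (the 0.2-1.25 Hz range) lying entirely inside
#' artifact-free included NREM time; the most negative and most positive
#' excursions of each cycle are recorded. (2) Selection: cycles whose
#' negative peak is strictly below the candidate-mean negative peak AND
#' whose peak-to-peak amplitude strictly exceeds the candidate-mean
#' peak-to-peak amplitude (means taken per channel per night over the
#' duration-valid candidates).
#'
#' @param x preprocessed signal of one channel (microvolts).
#' @param mask NREM `epoch_mask`.
#' @param rate sampling rate, Hz.
#' @param cfg configuration (`so$dur_s`, `filter$so_lowpass_hz`).
#' @param channel label stored with the events.
#' @return data.frame of SO events: `channel`, `start_s`, `end_s`,
#'   `neg_peak_s`, `neg_peak_uv`, `pos_peak_s`, `pos_peak_uv`,
#'   `duration_s`, `p2p_uv`.
#' @export
detect_sos <- function(x, mask, rate, cfg = default_config(),
                       channel = NA_character_) {
  lp <- lowpass_zero_phase(x, rate, cfg$filter$so_lowpass_hz,
                           transition = cfg$filter$so_lowpass_transition)
  empty <- data.frame(channel = character(0), start_s = numeric(0),
                      end_s = numeric(0), neg_peak_s = numeric(0),
                      neg_peak_uv = numeric(0), pos_peak_s = numeric(0),
                      pos_peak_uv = numeric(0), duration_s = numeric(0),
                      p2p_uv = numeric(0), stringsAsFactors = FALSE)
  n <- length(lp)
  # positive-to-negative zero crossings: sample i > 0, sample i+1 <= 0
  pn <- which(lp[-n] > 0 & lp[-1] <= 0)
  if (length(pn) < 2L) return(empty)
  inc <- sample_inclusion(mask, rate, n, exclude_artifacts = TRUE)
  dur_lim <- cfg$so$dur_s

  cyc_s <- pn[-length(pn)] + 1L
  cyc_e <- pn[-1L]
  dur <- (cyc_e - cyc_s + 1L) / rate
  ok <- dur >= dur_lim[1] & dur <= dur_lim[2]
  cand <- which(ok)
  if (!length(cand)) return(empty)
  rows <- lapply(cand, function(i) {
    a <- cyc_s[i]; b <- cyc_e[i]
    if (!all(inc[a:b])) return(NULL)
    seg <- lp[a:b]
    ineg <- which.min(seg); ipos <- which.max(seg)
    data.frame(channel = channel,
               start_s = (a - 1L) / rate, end_s = b / rate,
               neg_peak_s = (a - 1L + ineg - 1L) / rate,
               neg_peak_uv = seg[ineg],
               pos_peak_s = (a - 1L + ipos - 1L) / rate,
               pos_peak_uv = seg[ipos],
               duration_s = dur[i], p2p_uv = seg[ipos] - seg[ineg],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  cands <- do.call(rbind, rows)
  # strict inequalities, with a relative tolerance so numerically identical
  # cycles (round-off from FFT filtering) never pass as "strictly" extreme
  m_neg <- mean(cands$neg_peak_uv)
  m_p2p <- mean(cands$p2p_uv)
  tol_neg <- 1e-8 * abs(m_neg)
  tol_p2p <- 1e-8 * m_p2p
  sel <- cands$neg_peak_uv < m_neg - tol_neg & cands$p2p_uv > m_p2p + tol_p2p
  cands[sel, , drop = FALSE]
}

#' Instantaneous SO-band phase
#'
#' Band-passes to the SO range (0.2-1.25 Hz), Hilbert-transforms, and
#' returns the instantaneous phase: 0 at the positive SO peak, +pi/2 at the
#' falling zero crossing, +/-pi at the trough, increasing through the cycle.
#'
#' @param x preprocessed signal (microvolts).
#' @param rate sampling rate, Hz.
#' @param cfg configuration (`bands$so`, `filter$so_phase_transition`).
#' @return phase in radians, (-pi, pi], one value per sample.
#' @export
so_phase <- function(x, rate, cfg = default_config()) {
  band <- cfg$bands$so
  so <- bandpass_zero_phase(x, rate, band[1], band[2],
                            transition = cfg$filter$so_phase_transition)
  Arg(hilbert_analytic(so))
}

#' Pair spindles with the SO cycle containing their peak
#'
#' A spindle pairs with the (unique, cycles being disjoint) SO whose span
#' `[start_s, end_s)` contains the spindle amplitude peak. The coupling
#' phase is the SO-band instantaneous phase at the spindle-peak sample;
#' the coupling distance is its absolute value.
#'
#' @param sos SO event data.frame from [detect_sos()].
#' @param spindles spindle event data.frame from [detect_spindles()].
#' @param phase per-sample phase from [so_phase()] (same channel).
#' @param rate sampling rate, Hz.
#' @return data.frame: `channel`, `spindle_peak_s`, `so_start_s`,
#'   `so_end_s`, `phase_rad`, `distance_rad`.
#' @export
pair_so_spindles <- function(sos, spindles, phase, rate) {
  empty <- data.frame(channel = character(0), spindle_peak_s = numeric(0),
                      so_start_s = numeric(0), so_end_s = numeric(0),
                      phase_rad = numeric(0), distance_rad = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(sos) || !nrow(spindles)) return(empty)
  rows <- lapply(seq_len(nrow(spindles)), function(i) {
    pk <- spindles$peak_s[i]
    hit <- which(sos$start_s <= pk & pk < sos$end_s)
    if (length(hit) > 1L) stop("overlapping SO cycles; detector invariant broken")
    if (!length(hit)) return(NULL)
    idx <- min(length(phase), floor(pk * rate) + 1L)
    ph <- phase[idx]
    data.frame(channel = spindles$channel[i], spindle_peak_s = pk,
               so_start_s = sos$start_s[hit], so_end_s = sos$end_s[hit],
               phase_rad = ph, distance_rad = abs(ph),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Circular mean of angles
#' @param theta angles in radians.
#' @return mean direction in (-pi, pi].
#' @export
circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

#' Mean resultant length of angles
#' @param theta angles in radians.
#' @return resultant length in [0, 1].
#' @export
circ_r <- function(theta) sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)

#' Rayleigh test of circular uniformity
#'
#' Standard approximation to the Rayleigh p-value:
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n * rbar`.
#'
#' @param theta angles in radians (n >= 2).
#' @return list with `n`, `rbar`, `z` (= n rbar^2) and `p_value`.
#' @export
rayleigh_test <- function(theta) {
  n <- length(theta)
  if (n < 2L) stop("Rayleigh test requires at least 2 angles", call. = FALSE)
  rbar <- circ_r(theta)
  R <- n * rbar
  z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(n = n, rbar = rbar, z = z, p_value = min(1, max(p, .Machine$double.xmin)))
}

#' Summarize SO-spindle coupling for one channel
#'
#' @param pairs data.frame from [pair_so_spindles()].
#' @param channel label (defaults to the pairs' channel).
#' @return one-row data.frame: `channel`, `n_pairs`, `mean_distance_rad`,
#'   `circ_mean_phase_rad`, `rayleigh_p`. With no pairs every statistic is
#'   `NA` (an undefined summary propagates as missing, never as zero).
#' @export
coupling_summary <- function(pairs, channel = NULL) {
  if (is.null(channel))
    channel <- if (nrow(pairs)) pairs$channel[1] else NA_character_
  if (!nrow(pairs))
    return(data.frame(channel = channel, n_pairs = 0L,
                      mean_distance_rad = NA_real_,
                      circ_mean_phase_rad = NA_real_, rayleigh_p = NA_real_,
                      stringsAsFactors = FALSE))
  ph <- pairs$phase_rad
  data.frame(channel = channel, n_pairs = length(ph),
             mean_distance_rad = mean(abs(ph)),
             circ_mean_phase_rad = circ_mean(ph),
             rayleigh_p = if (length(ph) >= 2L) rayleigh_test(ph)$p_value else NA_real_,
             stringsAsFactors = FALSE)
}
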