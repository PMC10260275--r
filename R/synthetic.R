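# Synthetic polysomnography and recognition-response generator with known
# ground truth. Emulates the study conditions end to end: 1/f background
# EEG with injected 13-16 Hz spindle bursts and slow-oscillation cycles
# coupled at controllable phases, hemispherically asymmetric REM theta,
# artifact segments, subject covariates, and three-alternative response
# tables driven by an equal-variance signal-detection model.

#' Simulation specification
#'
#' All generator knobs with their default study conditions: 32 subjects,
#' 256 Hz, six-channel montage, stage architecture near the observed night
#' composition (N2 36%, N3 24%, REM 18%), 3.3 spindles/min at 13-16 Hz,
#' 4 SOs/min of ~150 uV peak-to-peak, 70% of spindles phase-locked near the
#' SO positive peak (mean phase about -2 degrees, concentration giving a
#' mean coupling distance near 0.95 rad), and a memory model whose target
#' strengths decline over retrievals with the 24-h emotional deficit driven
#' by a criterion shift for emotional foils. Nights default to a reduced
#' 60-min length; pass `night_min = 480` for a full night.
#'
#' @param ... named overrides with dotted paths, e.g.
#'   `spindle.rate_per_min = 2`, `night_min = 30`.
#' @return nested list of class `simulation_spec`.
#' @export
simulation_spec <- function(...) {
  spec <- list(
    n_subjects = 32L,
    rate = 256,
    night_min = 60,
    channels = c("F3", "F4", "C3", "C4", "A1", "A2"),
    stage_frac = c(N1 = 0.06, N2 = 0.36, N3 = 0.24, REM = 0.18),
    noise = list(slope = 1, rms_uv = 15, mastoid_rms_uv = 3),
    spindle = list(rate_per_min = 3.3, amp_factor = 20, freq = c(13, 16),
                   dur_s = c(0.6, 1.1), asym_mean = 0, asym_sd = 0.25),
    so = list(rate_per_min = 4, amp_uv = 75, amp_jitter = 0.15,
              period_s = c(0.9, 1.4)),
    coupling = list(frac = 0.7, phi0 = -0.04, kappa = 1.2,
                    asym_mean = 0, asym_sd = 0.25),
    theta = list(amp_uv = 7, freq = c(4, 7), asym_mean = 0, asym_sd = 0.25),
    artifact = list(epoch_frac = 0.05, dur_s = c(1, 12)),
    memory = list(strength_neutral = c(2.6, 2.1, 2.06),
                  strength_emotional = c(2.55, 2.0, 2.0),
                  c_old = 1.1, c_rec = 1.9,
                  emo_fa_shift_24h = 0.45,
                  subj_ability_sd = 0.35, subj_emo_sd = 0.3),
    wiring = list(coupling_to_emotion = -0.8, spindle_to_emotion_24h = 0.8)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    spec <- assign_path(spec, path, dots[[nm]])
  }
  if (sum(spec$stage_frac) > 1 + 1e-9)
    stop("stage fractions must sum to at most 1", call. = FALSE)
  stopifnot(spec$spindle$rate_per_min >= 0, spec$so$rate_per_min >= 0,
            spec$coupling$kappa >= 0, spec$noise$rms_uv > 0)
  nyq <- spec$rate / 2
  if (spec$spindle$freq[2] >= nyq || 1 / spec$so$period_s[1] >= nyq)
    stop("injection bands must lie below Nyquist", call. = FALSE)
  class(spec) <- c("simulation_spec", "list")
  spec
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` gives the circular uniform
#' distribution (the null for Rayleigh calibration).
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      s <- if (stats::runif(1) > 0.5) 1 else -1
      out[i] <- s * acos(pmin(1, pmax(-1, f))) + mu
    }
  }
  wrap_pi(out)
}

#' Expected absolute phase under a von Mises law
#'
#' `E|phi|` for phi ~ vonMises(mu, kappa); pi/2 at kappa = 0 (uniform),
#' approaching |mu| as kappa grows.
#'
#' @param kappa concentration.
#' @param mu mean direction.
#' @return expected absolute deviation from phase 0, radians.
#' @export
vm_mean_abs_phase <- function(kappa, mu = 0) {
  if (kappa < 1e-8) return(pi / 2)
  dens <- function(t) exp(kappa * (cos(t - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  stats::integrate(function(t) abs(t) * dens(t), -pi, pi,
                   rel.tol = 1e-8)$value
}

# invert vm_mean_abs_phase in kappa for a target mean coupling distance
kappa_for_distance <- function(target, mu = 0) {
  lo <- 1e-3; hi <- 200
  f <- function(k) vm_mean_abs_phase(k, mu) - target
  if (f(lo) <= 0) return(lo)
  if (f(hi) >= 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' 1/f (pink) background noise
#'
#' Spectrally shaped Gaussian noise: amplitude scaled as f^(-slope/2),
#' zero-mean, rescaled to the requested RMS.
#'
#' @param n samples.
#' @param slope spectral exponent of the power spectrum (1 = pink).
#' @param rms target root-mean-square amplitude.
#' @return numeric vector.
#' @export
pink_noise <- function(n, slope = 1, rms = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)
  scale <- c(0, f[-1]^(-slope / 2))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# staged hypnogram: leading/trailing wake around repeated N1-N2-N3-N2-REM
# cycles whose per-stage epoch counts realize the target fractions
simulate_hypnogram <- function(spec, n_epochs) {
  fr <- spec$stage_frac
  counts <- round(fr * n_epochs)
  n_w <- n_epochs - sum(counts)
  if (n_w < 0) { counts["N2"] <- counts["N2"] + n_w; n_w <- 0 }
  ncyc <- max(1L, min(4L, counts["REM"], counts["N2"]))
  split_even <- function(total, parts) {
    base <- total %/% parts
    extra <- total - base * parts
    base + c(rep(1L, extra), rep(0L, parts - extra))
  }
  per <- lapply(c("N1", "N2", "N3", "REM"),
                function(s) split_even(counts[[s]], ncyc))
  names(per) <- c("N1", "N2", "N3", "REM")
  stages <- rep("W", n_w %/% 2)
  for (i in seq_len(ncyc)) {
    n2a <- per$N2[i] %/% 2
    stages <- c(stages, rep("N1", per$N1[i]), rep("N2", n2a),
                rep("N3", per$N3[i]), rep("N2", per$N2[i] - n2a),
                rep("REM", per$REM[i]))
  }
  stages <- c(stages, rep("W", n_epochs - length(stages)))
  hypnogram(stages, 30)
}

# injected SO waveform: three cycles of -sin(2 pi t / T) under a Hann
# taper; the full-amplitude central cycle is the slow oscillation proper,
# the tapered flanks keep the band-passed signal locally oscillatory so
# its Hilbert phase sweeps the whole circle within the central cycle
so_waveform <- function(T_, rate) {
  len <- round(3 * T_ * rate)
  tt <- (seq_len(len) - 1) / rate
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
  -w * sin(2 * pi * tt / T_)
}

# instantaneous SO-band phase across the central cycle of the injected
# waveform: the band-pass filter distorts the phase progression, so
# injection places coupled spindles by looking up the target phase in
# this measured profile rather than assuming uniform advance
so_cycle_phase_profile <- function(T_, rate) {
  pad <- 8
  wav <- so_waveform(T_, rate)
  n <- round(2 * pad * rate) + length(wav)
  x <- numeric(n)
  a <- round(pad * rate) + 1L
  x[a:(a + length(wav) - 1L)] <- wav
  ph <- Arg(hilbert_analytic(bandpass_zero_phase(x, rate, 0.2, 1.25,
                                                 transition = 0.2)))
  cyc <- round(T_ * rate)
  ph[(a + cyc):(a + 2L * cyc - 1L)]
}

hann_burst <- function(n_samp, freq, rate, phase = 0) {
  t <- (seq_len(n_samp) - 1) / rate
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_samp) - 1) / (n_samp - 1))
  w * sin(2 * pi * freq * t + phase)
}

#' Simulate one subject night of polysomnography
#'
#' Generates 1/f background on each channel, injects slow-oscillation
#' cycles (a full negative-then-positive sine cycle between two
#' positive-to-negative zero crossings) into the four EEG channels during
#' NREM, injects Hann-windowed fast-spindle bursts (a per-spec fraction
#' phase-locked to the SO phase, the rest at random NREM times), adds
#' asymmetric theta oscillations to the frontal channels in REM, marks a
#' fraction of sleep epochs with artifact intervals, and returns the
#' detector-independent ground truth of every injected event.
#'
#' Spindle burst amplitude is `amp_factor` times the channel background's
#' rectified spindle-band mean, so injections are expressed in units of the
#' detection threshold (upper threshold ~ 5x that mean).
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed for this night.
#' @param lat optional list of subject lateralization values
#'   (`spindle`, `spindle_central`, `coupling`, `theta`); drawn from the
#'   spec's asymmetry distributions when omitted.
#' @return list: `recording`, `hypnogram`, `artifacts`, `truth` (lists
#'   `spindles`, `sos`, `lat`, `m_bg`).
#' @export
simulate_night <- function(spec = simulation_spec(), seed = 1, lat = NULL) {
  set.seed(seed)
  rate <- spec$rate
  n_epochs <- as.integer(round(spec$night_min * 2))
  hyp <- simulate_hypnogram(spec, n_epochs)
  n <- n_epochs * 30L * rate
  chans <- spec$channels
  eeg_ch <- intersect(c("F3", "F4", "C3", "C4"), chans)

  if (is.null(lat)) {
    lat <- list(
      spindle = stats::rnorm(1, spec$spindle$asym_mean, spec$spindle$asym_sd),
      spindle_central = stats::rnorm(1, 0, spec$spindle$asym_sd),
      coupling = stats::rnorm(1, spec$coupling$asym_mean, spec$coupling$asym_sd),
      theta = stats::rnorm(1, spec$theta$asym_mean, spec$theta$asym_sd))
  }

  data <- matrix(0, nrow = n, ncol = length(chans))
  colnames(data) <- chans
  for (ch in chans) {
    rms <- if (ch %in% c("A1", "A2")) spec$noise$mastoid_rms_uv else spec$noise$rms_uv
    data[, ch] <- pink_noise(n, spec$noise$slope, rms)
  }

  # background spindle-band rectified mean per EEG channel (from the first
  # two minutes of clean background, before any injection)
  m_bg <- vapply(eeg_ch, function(ch) {
    seg <- data[seq_len(min(n, 120L * rate)), ch]
    mean(abs(spindle_band_filter(seg, rate)))
  }, numeric(1))

  nrem_ep <- which(hyp$stages %in% c("N2", "N3"))
  rem_ep <- which(hyp$stages == "REM")
  sleep_ep <- which(hyp$stages != "W")

  # --- slow oscillations (common to the four EEG channels) ---
  so_rows <- list()
  if (spec$so$rate_per_min > 0 && length(nrem_ep)) {
    for (ep in nrem_ep) {
      k <- min(6L, stats::rpois(1, spec$so$rate_per_min * 0.5))
      if (k == 0L) next
      slots <- sort(sample.int(6L, k))         # 5-s slots inside the epoch
      for (s in slots) {
        T_ <- stats::runif(1, spec$so$period_s[1], spec$so$period_s[2])
        t0 <- (ep - 1L) * 30 + (s - 1L) * 5 +
          stats::runif(1, 0, max(0, 5 - 3 * T_))
        A <- spec$so$amp_uv *
          (1 + stats::runif(1, -spec$so$amp_jitter, spec$so$amp_jitter))
        a <- floor(t0 * rate) + 1L
        wave <- A * so_waveform(T_, rate)
        len <- length(wave)
        if (a + len - 1L > n) next
        for (ch in eeg_ch) data[a:(a + len - 1L), ch] <-
            data[a:(a + len - 1L), ch] + wave
        cyc_start <- (a - 1L) / rate + T_      # central full-amplitude cycle
        so_rows[[length(so_rows) + 1L]] <-
          data.frame(epoch = ep, start_s = cyc_start,
                     end_s = cyc_start + T_, period_s = T_,
                     amp_uv = A,
                     pos_peak_s = cyc_start + 0.75 * T_,
                     stringsAsFactors = FALSE)
      }
    }
  }
  so_truth <- if (length(so_rows)) do.call(rbind, so_rows) else
    data.frame(epoch = integer(0), start_s = numeric(0), end_s = numeric(0),
               period_s = numeric(0), amp_uv = numeric(0),
               pos_peak_s = numeric(0))

  # --- spindles ---
  ch_rate <- c(F3 = spec$spindle$rate_per_min * (1 - lat$spindle / 2),
               F4 = spec$spindle$rate_per_min * (1 + lat$spindle / 2),
               C3 = spec$spindle$rate_per_min * (1 - lat$spindle_central / 2),
               C4 = spec$spindle$rate_per_min * (1 + lat$spindle_central / 2))
  ch_rate <- ch_rate[eeg_ch]
  ch_rate[] <- pmax(0, ch_rate)
  d0 <- vm_mean_abs_phase(spec$coupling$kappa, spec$coupling$phi0)
  targ <- c(F3 = d0 * (1 - lat$coupling / 2), F4 = d0 * (1 + lat$coupling / 2),
            C3 = d0, C4 = d0)
  targ[] <- pmin(pi / 2 - 0.05, pmax(abs(spec$coupling$phi0) + 0.02, targ))
  ch_kappa <- vapply(eeg_ch, function(ch)
    kappa_for_distance(targ[[ch]], spec$coupling$phi0), numeric(1))

  sp_rows <- list()
  tmpl_cache <- new.env(parent = emptyenv())
  phase_to_offset <- function(T_, phi) {
    key <- sprintf("%.2f", T_)
    prof <- tmpl_cache[[key]]
    if (is.null(prof)) {
      prof <- so_cycle_phase_profile(round(T_, 2), rate)
      tmpl_cache[[key]] <- prof
    }
    idx <- which.min(abs(wrap_pi(prof - phi)))
    (idx - 1L) / rate
  }
  inject_burst <- function(ch, t_peak, dur, freq) {
    A <- spec$spindle$amp_factor * m_bg[[ch]]
    len <- round(dur * rate)
    if (len %% 2L == 0L) len <- len + 1L
    a <- round(t_peak * rate) + 1L - (len - 1L) %/% 2L
    if (a < 1L || a + len - 1L > n) return(NULL)
    burst <- A * hann_burst(len, freq, rate, phase = pi / 2)  # peak at center
    data[a:(a + len - 1L), ch] <<- data[a:(a + len - 1L), ch] + burst
    data.frame(channel = ch, peak_s = t_peak, start_s = (a - 1L) / rate,
               end_s = (a - 1L + len) / rate, amp_uv = A, freq_hz = freq,
               stringsAsFactors = FALSE)
  }
  for (ch in eeg_ch) {
    coupled_n <- 0L
    if (spec$coupling$frac > 0 && nrow(so_truth)) {
      # hemisphere rate asymmetry applies to coupled spindles too
      rel <- if (spec$spindle$rate_per_min > 0)
        ch_rate[[ch]] / spec$spindle$rate_per_min else 1
      p_c <- min(1, spec$coupling$frac * rel)
      pick <- which(stats::runif(nrow(so_truth)) < p_c)
      for (i in pick) {
        phi <- rvonmises(1, spec$coupling$phi0, ch_kappa[[ch]])
        t_peak <- so_truth$start_s[i] +
          phase_to_offset(so_truth$period_s[i], phi)
        dur <- stats::runif(1, spec$spindle$dur_s[1], spec$spindle$dur_s[2])
        freq <- stats::runif(1, spec$spindle$freq[1], spec$spindle$freq[2])
        row <- inject_burst(ch, t_peak, dur, freq)
        if (!is.null(row)) {
          row$coupled <- TRUE; row$phase_rad <- phi; row$so_idx <- i
          sp_rows[[length(sp_rows) + 1L]] <- row
          coupled_n <- coupled_n + 1L
        }
      }
    }
    target_n <- stats::rpois(1, ch_rate[[ch]] * 0.5 * length(nrem_ep))
    n_unc <- max(0L, target_n - coupled_n)
    if (n_unc > 0L && length(nrem_ep)) {
      eps <- sample(nrem_ep, n_unc, replace = TRUE)
      for (ep in eps) {
        dur <- stats::runif(1, spec$spindle$dur_s[1], spec$spindle$dur_s[2])
        t_peak <- (ep - 1L) * 30 + stats::runif(1, dur, 30 - dur)
        freq <- stats::runif(1, spec$spindle$freq[1], spec$spindle$freq[2])
        row <- inject_burst(ch, t_peak, dur, freq)
        if (!is.null(row)) {
          row$coupled <- FALSE; row$phase_rad <- NA_real_; row$so_idx <- NA_integer_
          sp_rows[[length(sp_rows) + 1L]] <- row
        }
      }
    }
  }
  sp_truth <- if (length(sp_rows)) do.call(rbind, sp_rows) else
    data.frame(channel = character(0), peak_s = numeric(0),
               start_s = numeric(0), end_s = numeric(0), amp_uv = numeric(0),
               freq_hz = numeric(0), coupled = logical(0),
               phase_rad = numeric(0), so_idx = integer(0))

  # --- REM theta, frontal, right/left asymmetric ---
  # band-limited (4-7 Hz) Gaussian oscillatory activity spanning the whole
  # theta band, independent per channel, scaled to the spec RMS with the
  # hemisphere asymmetry factor
  th_amp <- c(F3 = spec$theta$amp_uv * (1 - lat$theta / 2),
              F4 = spec$theta$amp_uv * (1 + lat$theta / 2))
  if (length(rem_ep) && spec$theta$amp_uv > 0) {
    fr <- spec$theta$freq
    for (ch in intersect(c("F3", "F4"), chans)) {
      th <- bandpass_zero_phase(stats::rnorm(n), rate, fr[1], fr[2],
                                transition = 1)
      th <- th / stats::sd(th) * th_amp[[ch]]
      for (ep in rem_ep) {
        a <- (ep - 1L) * 30L * rate + 1L
        b <- min(n, ep * 30L * rate)
        data[a:b, ch] <- data[a:b, ch] + th[a:b]
      }
    }
  }

  # --- artifacts ---
  n_art <- round(spec$artifact$epoch_frac * length(sleep_ep))
  art <- artifact_set()
  if (n_art > 0L) {
    eps <- sample(sleep_ep, n_art)
    dur <- stats::runif(n_art, spec$artifact$dur_s[1],
                        min(29, spec$artifact$dur_s[2]))
    off <- stats::runif(n_art, 0, 30 - dur)
    art <- artifact_set((eps - 1L) * 30 + off, (eps - 1L) * 30 + off + dur)
  }

  list(recording = psg_recording(data, chans, rate),
       hypnogram = hyp, artifacts = art,
       truth = list(spindles = sp_truth, sos = so_truth, lat = lat,
                    m_bg = m_bg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-subject memory parameters: base strengths + ability/emotion traits +
# lateralization wiring (coupling -> overall emotional difference,
# spindle lateralization -> 24-h emotional difference)
subject_memory_params <- function(spec, lat) {
  mem <- spec$memory
  g <- stats::rnorm(1, 0, mem$subj_ability_sd)
  e_t <- stats::rnorm(1, 0, mem$subj_emo_sd)
  shift_all <- e_t + spec$wiring$coupling_to_emotion * lat$coupling
  shift_24 <- spec$wiring$spindle_to_emotion_24h * lat$spindle
  neu <- mem$strength_neutral + g + shift_all / 2
  emo <- mem$strength_emotional + g - shift_all / 2
  neu[3] <- neu[3] + shift_24 / 2
  emo[3] <- emo[3] - shift_24 / 2
  list(strength = rbind(neutral = neu, emotional = emo),
       c_old = mem$c_old, c_rec = mem$c_rec,
       emo_fa_shift_24h = mem$emo_fa_shift_24h)
}

#' Simulate a recognition response table for one subject
#'
#' Equal-variance signal-detection model: target strength ~ N(d_true, 1),
#' foil strength ~ N(0, 1); responses by dual criteria (recollected above
#' `c_rec`, familiar between `c_old` and `c_rec`, otherwise new). At the
#' 24-h retrieval the criteria for emotional foils are lowered by
#' `emo_fa_shift_24h`, inflating emotional false alarms without touching
#' hit rates. Emits the exact task structure: 3 retrievals x (25 targets +
#' 25 foils) x 2 emotions.
#'
#' @param spec a [simulation_spec()].
#' @param params per-subject memory parameters (see
#'   [simulate_cohort()]); built from the spec defaults when `NULL`.
#' @param seed RNG seed.
#' @param subject subject identifier for the table.
#' @param n_per_cell targets (= foils) per emotion cell; 25 is the task
#'   design, larger values support large-n recovery checks.
#' @return response data.frame (see [read_responses()] for columns).
#' @export
simulate_responses <- function(spec = simulation_spec(), params = NULL,
                               seed = 1, subject = "s01", n_per_cell = 25L) {
  set.seed(seed)
  if (is.null(params))
    params <- list(strength = rbind(neutral = spec$memory$strength_neutral,
                                    emotional = spec$memory$strength_emotional),
                   c_old = spec$memory$c_old, c_rec = spec$memory$c_rec,
                   emo_fa_shift_24h = spec$memory$emo_fa_shift_24h)
  if (params$c_old >= params$c_rec)
    stop("criteria out of order: c_old must be below c_rec", call. = FALSE)
  rows <- list()
  for (r in seq_along(RETRIEVALS)) {
    for (e in seq_along(EMOTIONS)) {
      d <- params$strength[e, r]
      shift <- if (r == 3L && e == 2L) params$emo_fa_shift_24h else 0
      s_t <- stats::rnorm(n_per_cell, d, 1)
      s_f <- stats::rnorm(n_per_cell, 0, 1)
      classify <- function(s, c_old, c_rec)
        ifelse(s > c_rec, "recollected", ifelse(s > c_old, "familiar", "new"))
      resp_t <- classify(s_t, params$c_old, params$c_rec)
      resp_f <- classify(s_f, params$c_old - shift, params$c_rec - shift)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, retrieval = RETRIEVALS[r],
        item_id = sprintf("%s_%s_%s_%03d", RETRIEVALS[r], EMOTIONS[e],
                          rep(c("t", "f"), each = n_per_cell),
                          c(seq_len(n_per_cell), seq_len(n_per_cell))),
        emotion = EMOTIONS[e],
        is_target = rep(c(TRUE, FALSE), each = n_per_cell),
        response = c(resp_t, resp_f), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate subject covariates
#'
#' Sex (~78% female), measurement location (home/laboratory), study-night
#' sleep duration (hours), right-skewed BDI and GAD-7 questionnaire scores
#' with their ln(x+1) transforms, and handedness with occasional missing
#' values.
#'
#' @param n subjects.
#' @param seed RNG seed.
#' @return data.frame with one row per subject.
#' @export
simulate_covariates <- function(n, seed = 1) {
  set.seed(seed)
  sex <- ifelse(stats::rbinom(n, 1, 25 / 32) == 1, "F", "M")
  location <- ifelse(stats::rbinom(n, 1, 17 / 32) == 1, "home", "lab")
  sleep_h <- pmin(9, pmax(4.3, stats::rnorm(n, 6.73, 0.75)))
  bdi <- pmin(45, round(stats::rgamma(n, shape = 1.2, scale = 9.5)))
  gad7 <- pmin(21, round(stats::rgamma(n, shape = 1.7, scale = 3.3)))
  handed <- sample(c("right", "left", "ambidextrous", NA),
                   n, replace = TRUE, prob = c(26, 1, 1, 4) / 32)
  data.frame(subject = sprintf("s%02d", seq_len(n)), sex = sex,
             location = location, sleep_h = sleep_h,
             bdi = bdi, gad7 = gad7,
             bdi_ln = log(bdi + 1), gad7_ln = log(gad7 + 1),
             handedness = handed, stringsAsFactors = FALSE)
}

#' Simulate a full cohort bundle
#'
#' Draws per-subject lateralization values, generates (optionally) one
#' synthetic night per subject, simulates responses with the
#' lateralization-to-memory wiring applied, and returns everything with
#' the ground truth. With `eeg = FALSE` only the behavioral arm is
#' generated (used for large-replicate statistical calibration where the
#' oscillatory covariate enters at its true value).
#'
#' @param spec a [simulation_spec()].
#' @param seed master seed; per-subject seeds derive from it.
#' @param eeg generate the polysomnography arm.
#' @return list: `spec`, `covariates` (with true lateralization columns
#'   `spindle_lat_true`, `coupling_lat_true`, `theta_lat_true`), `nights`
#'   (list, or NULL), `responses` (one long table), `truth` (per-subject
#'   list of night ground truths).
#' @export
simulate_cohort <- function(spec = simulation_spec(), seed = 1, eeg = TRUE) {
  set.seed(seed)
  n <- spec$n_subjects
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L * n)
  cov <- simulate_covariates(n, seed = sub_seeds[3L * n])
  lats <- lapply(seq_len(n), function(i) {
    list(spindle = stats::rnorm(1, spec$spindle$asym_mean, spec$spindle$asym_sd),
         spindle_central = stats::rnorm(1, 0, spec$spindle$asym_sd),
         coupling = stats::rnorm(1, spec$coupling$asym_mean, spec$coupling$asym_sd),
         theta = stats::rnorm(1, spec$theta$asym_mean, spec$theta$asym_sd))
  })
  cov$spindle_lat_true <- vapply(lats, `[[`, numeric(1), "spindle")
  cov$coupling_lat_true <- vapply(lats, `[[`, numeric(1), "coupling")
  cov$theta_lat_true <- vapply(lats, `[[`, numeric(1), "theta")

  mem_seeds <- sub_seeds[seq_len(n)]
  night_seeds <- sub_seeds[n + seq_len(n)]
  nights <- NULL
  truth <- vector("list", n)
  responses <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(mem_seeds[i])
    params <- subject_memory_params(spec, lats[[i]])
    responses[[i]] <- simulate_responses(spec, params, seed = mem_seeds[i] + 1L,
                                         subject = cov$subject[i])
  }
  if (eeg) {
    nights <- vector("list", n)
    for (i in seq_len(n)) {
      nights[[i]] <- simulate_night(spec, seed = night_seeds[i], lat = lats[[i]])
      truth[[i]] <- nights[[i]]$truth
      names(nights)[i] <- cov$subject[i]
    }
  }
  list(spec = spec, covariates = cov, nights = nights,
       responses = do.call(rbind, responses), truth = truth)
}

#' Fast score-level cohort simulation
#'
#' Bypasses the item-level response tables: per subject x retrieval x
#' emotion cell, hits ~ Binomial(25, Phi(d - c_old)) and false alarms ~
#' Binomial(25, Phi(-c)) under the same signal-detection model as
#' [simulate_responses()], scored immediately into d'. Statistically
#' identical to scoring the full tables, and cheap enough for
#' many-replicate calibration studies.
#'
#' @param spec a [simulation_spec()].
#' @param seed RNG seed.
#' @param n_per_cell trials per cell.
#' @return list: `d_array` (n x 3 x 2), `covariates` (with true
#'   lateralization columns).
#' @export
simulate_score_cohort <- function(spec = simulation_spec(), seed = 1,
                                  n_per_cell = 25L) {
  set.seed(seed)
  n <- spec$n_subjects
  cov <- simulate_covariates(n, seed = seed + 1L)
  set.seed(seed + 2L)
  arr <- array(NA_real_, dim = c(n, 3L, 2L),
               dimnames = list(subject = cov$subject,
                               retrieval = RETRIEVALS, emotion = EMOTIONS))
  lat_c <- stats::rnorm(n, spec$coupling$asym_mean, spec$coupling$asym_sd)
  lat_s <- stats::rnorm(n, spec$spindle$asym_mean, spec$spindle$asym_sd)
  lat_t <- stats::rnorm(n, spec$theta$asym_mean, spec$theta$asym_sd)
  cov$coupling_lat_true <- lat_c
  cov$spindle_lat_true <- lat_s
  cov$theta_lat_true <- lat_t
  for (i in seq_len(n)) {
    params <- subject_memory_params(spec, list(coupling = lat_c[i],
                                               spindle = lat_s[i],
                                               theta = lat_t[i]))
    for (r in 1:3) for (e in 1:2) {
      d <- params$strength[e, r]
      shift <- if (r == 3L && e == 2L) params$emo_fa_shift_24h else 0
      h <- stats::rbinom(1, n_per_cell, stats::pnorm(d - params$c_old))
      f <- stats::rbinom(1, n_per_cell, stats::pnorm(-(params$c_old - shift)))
      arr[i, r, e] <- dprime(h / n_per_cell, f / n_per_cell,
                             n_per_cell, n_per_cell)
    }
  }
  list(d_array = arr, covariates = cov)
}
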