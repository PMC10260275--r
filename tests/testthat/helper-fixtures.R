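# Shared fixtures, built in code at test time.

# recording of pure tones per channel; amps/freqs named by channel
tone_recording <- function(channels, freqs, amps, rate = 128, dur_s = 30) {
  t <- seq_len(rate * dur_s) / rate
  data <- vapply(channels, function(ch)
    amps[[ch]] * sin(2 * pi * freqs[[ch]] * t), numeric(length(t)))
  psg_recording(data, channels, rate)
}

# amplitude of a pure tone from its RMS (grid-independent)
tone_amplitude <- function(x, rate = NULL, freq = NULL) {
  sqrt(2 * mean(x^2))
}

# spindle-band-like trace: baseline sine with burst envelopes; bursts is a
# data.frame(center_s, dur_s, amp) on top of a baseline-amplitude carrier
burst_trace <- function(rate, dur_s, f = 14, baseline = 1, bursts = NULL,
                        ramp_s = 0.08) {
  n <- rate * dur_s
  t <- (seq_len(n) - 1) / rate
  env <- rep(baseline, n)
  if (!is.null(bursts)) for (i in seq_len(nrow(bursts))) {
    b <- bursts[i, ]
    a <- b$center_s - b$dur_s / 2
    ramp_up <- t >= a - ramp_s & t < a
    ramp_dn <- t >= a + b$dur_s & t < a + b$dur_s + ramp_s
    core <- t >= a & t < a + b$dur_s
    # near-flat plateau with a slight central dome so the amplitude
    # maximum (the flank-rule anchor) sits mid-burst, as in real spindles
    env[core] <- b$amp * (1 + 0.08 * sin(pi * (t[core] - a) / b$dur_s))
    env[ramp_up] <- baseline + (b$amp - baseline) * (t[ramp_up] - (a - ramp_s)) / ramp_s
    env[ramp_dn] <- b$amp + (baseline - b$amp) * (t[ramp_dn] - (a + b$dur_s)) / ramp_s
  }
  env * sin(2 * pi * f * t)
}

# all-NREM mask over a given duration with no artifacts
clean_nrem_mask <- function(dur_s, cfg = default_config()) {
  hyp <- hypnogram(rep("N2", dur_s %/% 30), 30)
  build_epoch_mask(hyp, artifact_set(), c("N2", "N3"), cfg)
}

# alternating-amplitude slow-oscillation train: full cycles of -sin with
# per-cycle amplitudes, period T
so_train <- function(amps, T_ = 1.25, rate = 128) {
  len <- round(T_ * rate)
  tt <- (seq_len(len) - 1) / rate
  unlist(lapply(amps, function(a) -a * sin(2 * pi * tt / T_)))
}
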