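test_that("a pure sinusoid yields candidates but no selected SOs", {
  rate <- 128
  cfg <- default_config()
  # wake epochs at both ends keep filter edge transients out of the mask,
  # so every included cycle is exactly identical
  hyp <- hypnogram(c("W", rep("N2", 2), "W"), 30)
  mask <- build_epoch_mask(hyp, artifact_set(), c("N2", "N3"), cfg)
  t <- seq_len(rate * 120) / rate
  x <- 60 * sin(2 * pi * 1 * t)
  # identical cycles: nothing is strictly below/above the candidate means
  expect_equal(nrow(detect_sos(x, mask, rate, cfg)), 0)
})

test_that("alternating amplitude classes: exactly the large cycles survive", {
  rate <- 128
  cfg <- default_config()
  A <- 25
  amps <- rep(c(A, 3 * A), 40)
  x <- so_train(amps, T_ = 1.25, rate = rate)
  pad <- numeric(rate * 30)
  x <- c(pad, x, pad)
  dur_s <- ceiling(length(x) / rate / 30) * 30
  x <- c(x, numeric(dur_s * rate - length(x)))
  mask <- clean_nrem_mask(dur_s)
  sos <- detect_sos(x, mask, rate, cfg)
  # direct-computation oracle: candidate means fall between the classes,
  # so the 3A class and only it satisfies both strict inequalities
  expect_gt(nrow(sos), 0)
  expect_true(all(sos$p2p_uv > 4 * A))
  big_starts <- 30 + (which(amps == 3 * A) - 1) * 1.25
  expect_equal(nrow(sos), length(big_starts))
  expect_equal(sos$start_s, big_starts, tolerance = 0.05)
  expect_true(all(sos$neg_peak_uv < 0 & sos$pos_peak_uv > 0))
  expect_true(all(sos$duration_s >= 0.8 & sos$duration_s <= 5))
})

test_that("0.75 Hz cycles all fall inside the 0.8-5 s duration gate", {
  rate <- 128
  T_ <- 1 / 0.75
  x <- so_train(rep(c(20, 60), 20), T_ = T_, rate = rate)
  dur_s <- ceiling(length(x) / rate / 30) * 30
  x <- c(x, numeric(dur_s * rate - length(x)))
  mask <- clean_nrem_mask(dur_s)
  sos <- detect_sos(x, mask, 128, default_config())
  expect_gt(nrow(sos), 0)
  # amplitude alternation nudges the smoothed zero crossings slightly
  expect_equal(sos$duration_s, rep(T_, nrow(sos)), tolerance = 0.05)
  expect_true(all(sos$duration_s >= 0.8 & sos$duration_s <= 5))
})

test_that("the SO phase convention anchors 0 at the positive peak", {
  rate <- 128
  cfg <- default_config()
  t <- seq_len(rate * 400) / rate
  x <- 50 * cos(2 * pi * 1 * t)    # 1 Hz lies in the 0.2-1.25 band
  ph <- so_phase(x, rate, cfg)
  at <- function(s) ph[round(s * rate)]
  expect_lt(abs(at(200)), 0.05)                 # positive peak: phase 0
  expect_lt(abs(abs(at(200.5))) - pi, 0.05)     # trough: |phase| = pi
  expect_lt(abs(at(200.25) - pi / 2), 0.05)     # falling zero crossing: +pi/2
  expect_lt(abs(at(200.75) + pi / 2), 0.05)     # rising zero crossing: -pi/2
})

test_that("spindles pair only when their peak falls inside an SO cycle", {
  rate <- 128
  sos <- data.frame(channel = "F3", start_s = c(10, 20), end_s = c(11, 21),
                    neg_peak_s = c(10.25, 20.25), neg_peak_uv = -50,
                    pos_peak_s = c(10.75, 20.75), pos_peak_uv = 50,
                    duration_s = 1, p2p_uv = 100)
  spindles <- data.frame(channel = "F3", start_s = c(10.4, 14.6, 20.0),
                         end_s = c(11.2, 15.4, 20.8),
                         peak_s = c(10.75, 15.0, 20.4),
                         amplitude_uv = 20, duration_s = 0.8)
  t <- seq_len(rate * 30) / rate
  phase <- Arg(hilbert_analytic(cos(2 * pi * 1 * (t - 10.75))))
  pairs <- pair_so_spindles(sos, spindles, phase, rate)
  expect_equal(nrow(pairs), 2)                  # 15.0 s peak is outside
  expect_equal(pairs$distance_rad, abs(pairs$phase_rad))
  expect_lt(pairs$distance_rad[1], 0.05)        # at the positive peak
})

test_that("injected coupling at SO peak and trough is recovered", {
  # phase is read at the known injected peaks (ground truth), isolating the
  # pairing + phase machinery from spindle-peak localization jitter
  cfg <- default_config()
  base <- list(night_min = 20, channels = c("F3", "A1", "A2"),
               coupling.frac = 1, coupling.kappa = 500, noise.rms_uv = 3,
               spindle.rate_per_min = 0.01, so.rate_per_min = 8,
               artifact.epoch_frac = 0)
  for (case in list(list(phi = 0, lim = 0.15, low = TRUE),
                    list(phi = pi, lim = pi - 0.15, low = FALSE))) {
    spec <- do.call(simulation_spec, c(base, list(coupling.phi0 = case$phi)))
    nt <- simulate_night(spec, seed = 17)
    pre <- preprocess_recording(nt$recording, cfg)
    x <- pre$data[, channel_index(pre, "F3")]
    mask <- build_epoch_mask(nt$hypnogram, nt$artifacts, c("N2", "N3"), cfg)
    sos <- detect_sos(x, mask, spec$rate, cfg, channel = "F3")
    ph <- so_phase(x, spec$rate, cfg)
    tr <- nt$truth$spindles[nt$truth$spindles$coupled, ]
    sp <- data.frame(channel = "F3", start_s = tr$start_s, end_s = tr$end_s,
                     peak_s = tr$peak_s, amplitude_uv = tr$amp_uv,
                     duration_s = tr$end_s - tr$start_s)
    pairs <- pair_so_spindles(sos, sp, ph, spec$rate)
    expect_gt(nrow(pairs), 50)
    md <- mean(pairs$distance_rad)
    if (case$low) expect_lt(md, case$lim) else expect_gt(md, case$lim)
  }
})

test_that("coupling summaries use circular statistics", {
  pairs <- data.frame(channel = "F3", spindle_peak_s = 1:2, so_start_s = 0,
                      so_end_s = 3, phase_rad = c(0, pi / 2),
                      distance_rad = c(0, pi / 2))
  cs <- coupling_summary(pairs)
  expect_equal(cs$circ_mean_phase_rad, pi / 4)
  expect_equal(cs$mean_distance_rad, pi / 4)

  # empty pairs: undefined, propagated as missing, not zero
  cs0 <- coupling_summary(pairs[0, ], channel = "F3")
  expect_equal(cs0$n_pairs, 0L)
  expect_true(is.na(cs0$mean_distance_rad))
  expect_true(is.na(cs0$circ_mean_phase_rad))
})

test_that("Rayleigh test separates uniform from concentrated phases", {
  set.seed(21)
  unif <- runif(1000, -pi, pi)
  expect_gt(rayleigh_test(unif)$p_value, 0.05)
  conc <- rvonmises(1000, 0.3, 20)
  rt <- rayleigh_test(conc)
  expect_lt(rt$p_value, 0.001)
  expect_lt(abs(circ_mean(conc) - 0.3), 0.05)
})

test_that("reflecting phases preserves distance and negates the mean", {
  set.seed(22)
  ph <- rvonmises(300, 0.7, 3)
  mk <- function(p) data.frame(channel = "F3", spindle_peak_s = seq_along(p),
                               so_start_s = 0, so_end_s = 1e9,
                               phase_rad = p, distance_rad = abs(p))
  a <- coupling_summary(mk(ph)); b <- coupling_summary(mk(-ph))
  expect_equal(a$mean_distance_rad, b$mean_distance_rad)
  expect_equal(a$circ_mean_phase_rad, -b$circ_mean_phase_rad)
})
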