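test_that("spindle band filter passes 14.5 Hz and suppresses 10/20 Hz", {
  rate <- 256
  t <- seq_len(rate * 60) / rate
  edge <- 5000
  mid <- (edge + 1):(length(t) - edge)
  y <- spindle_band_filter(sin(2 * pi * 14.5 * t), rate)
  expect_lt(abs(tone_amplitude(y[mid], rate, 14.5) - 1), 0.02)
  for (f in c(10, 20)) {
    yf <- spindle_band_filter(sin(2 * pi * f * t), rate)
    expect_lt(tone_amplitude(yf[mid], rate, f), 0.05)
  }
})

test_that("the filter order scales with sampling rate and guards length", {
  expect_error(spindle_band_filter(numeric(1000), 256), "too short")
  # at 128 Hz the order halves; a short-but-sufficient signal passes
  y <- spindle_band_filter(numeric(3 * 1410), 128)
  expect_length(y, 3 * 1410)
})

test_that("thresholds are 5x and 2x the rectified NREM mean", {
  rate <- 128
  cfg <- default_config()
  mask <- clean_nrem_mask(120)
  n <- rate * 120
  sq <- rep(c(1, -1), length.out = n)            # |x| = 1 everywhere
  thr <- compute_thresholds(sq, mask, rate, cfg, "F3")
  expect_equal(thr$mean_amp_uv, 1)
  expect_equal(thr$upper, 5)
  expect_equal(thr$lower, 2)
  expect_equal(thr$upper / thr$lower, 2.5)

  # pure sine of amplitude A: mean |x| = 2A/pi (numeric rectified-mean oracle)
  A <- 7
  x <- A * sin(2 * pi * 14 * seq_len(n) / rate)
  thr2 <- compute_thresholds(x, mask, rate, cfg, "F3")
  oracle <- mean(abs(x))                          # -> 2A/pi as n grows
  expect_equal(thr2$mean_amp_uv, oracle)
  expect_equal(oracle, 2 * A / pi, tolerance = 1e-3)
  expect_equal(thr2$upper, 5 * oracle)

  # homogeneity: doubling the signal doubles all three values
  thr3 <- compute_thresholds(2 * x, mask, rate, cfg, "F3")
  expect_equal(thr3$mean_amp_uv, 2 * thr2$mean_amp_uv)
  expect_equal(thr3$upper, 2 * thr2$upper)
  expect_equal(thr3$lower, 2 * thr2$lower)
})

test_that("threshold estimation fails without included NREM samples", {
  cfg <- default_config()
  hyp <- hypnogram(rep("REM", 4), 30)
  mask <- build_epoch_mask(hyp, artifact_set(), c("N2", "N3"), cfg)
  expect_error(compute_thresholds(rnorm(128 * 120), mask, 128, cfg),
               "no included NREM")
})

test_that("a single injected burst is detected with its true extent", {
  rate <- 128
  cfg <- default_config()
  mask <- clean_nrem_mask(120)
  x <- burst_trace(rate, 120, f = 14, baseline = 1,
                   bursts = data.frame(center_s = 60, dur_s = 1.0, amp = 6 * 2 / pi))
  thr <- compute_thresholds(x, mask, rate, cfg, "F3")
  ev <- detect_spindles(x, thr, mask, rate, cfg)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$duration_s, 0.8)
  expect_lt(ev$duration_s, 1.2)
  expect_gt(ev$peak_s, 59.5)
  expect_lt(ev$peak_s, 60.5)
  expect_true(ev$start_s < ev$peak_s && ev$peak_s < ev$end_s)
})

test_that("zero signal yields no events", {
  rate <- 128
  cfg <- default_config()
  mask <- clean_nrem_mask(60)
  thr <- structure(list(channel = "F3", mean_amp_uv = 1, upper = 5, lower = 2),
                   class = "channel_thresholds")
  expect_equal(nrow(detect_spindles(numeric(rate * 60), thr, mask, rate, cfg)), 0)
})

test_that("sub-gap bursts merge and separated bursts stay distinct", {
  rate <- 256
  cfg <- default_config()
  mask <- clean_nrem_mask(120)
  amp <- 6 * 2 / pi
  mk <- function(gap_s) {
    # two 0.7-s bursts, second starting gap_s after the first ends
    c1 <- 60; c2 <- 60 + 0.35 + gap_s + 0.35
    burst_trace(rate, 120, f = 14, baseline = 0.2, ramp_s = 0.01,
                bursts = data.frame(center_s = c(c1, c2), dur_s = 0.7,
                                    amp = c(amp, 0.9 * amp)))
  }
  x50 <- mk(0.050)
  thr <- compute_thresholds(x50, mask, rate, cfg, "F3")
  ev50 <- detect_spindles(x50, thr, mask, rate, cfg)
  expect_equal(nrow(ev50), 1)                     # 50 ms < 78.1 ms: merged
  expect_gt(ev50$duration_s, 1.2)
  x150 <- mk(0.150)
  thr2 <- compute_thresholds(x150, mask, rate, cfg, "F3")
  ev150 <- detect_spindles(x150, thr2, mask, rate, cfg)
  expect_equal(nrow(ev150), 2)                    # 150 ms > 78.1 ms: separate
})

test_that("detection is invariant to rescaling, except the absolute cap", {
  rate <- 128
  cfg <- default_config()
  mask <- clean_nrem_mask(120)
  x <- burst_trace(rate, 120, f = 14, baseline = 1,
                   bursts = data.frame(center_s = c(30, 80), dur_s = c(0.8, 1.1),
                                       amp = 6 * 2 / pi))
  detect <- function(sig) {
    thr <- compute_thresholds(sig, mask, rate, cfg, "F3")
    detect_spindles(sig, thr, mask, rate, cfg)
  }
  e1 <- detect(x); e3 <- detect(3 * x)
  expect_equal(nrow(e1), 2)
  expect_equal(e3[c("start_s", "end_s", "peak_s")],
               e1[c("start_s", "end_s", "peak_s")])
  # the 200 uV cap is the only absolute rule
  e_big <- detect(80 * x)                         # bursts now exceed 200 uV
  expect_equal(nrow(e_big), 0)
})

test_that("events violating duration bounds or artifact overlap are dropped", {
  rate <- 128
  cfg <- default_config()
  x <- burst_trace(rate, 120, f = 14, baseline = 1,
                   bursts = data.frame(center_s = c(30, 80),
                                       dur_s = c(3.6, 1.0), amp = 6 * 2 / pi))
  mask <- clean_nrem_mask(120)
  thr <- compute_thresholds(x, mask, rate, cfg, "F3")
  ev <- detect_spindles(x, thr, mask, rate, cfg)
  expect_equal(nrow(ev), 1)                       # 3.6 s burst too long
  expect_gt(ev$peak_s, 79)

  # the surviving event dies once an artifact covers it
  hyp <- hypnogram(rep("N2", 4), 30)
  mask_art <- build_epoch_mask(hyp, artifact_set(79, 81), c("N2", "N3"), cfg)
  thr2 <- compute_thresholds(x, mask_art, rate, cfg, "F3")
  expect_equal(nrow(detect_spindles(x, thr2, mask_art, rate, cfg)), 0)
})

test_that("all detected events honor the construction invariants", {
  spec <- simulation_spec(night_min = 10, channels = c("F3", "A1", "A2"))
  nt <- simulate_night(spec, seed = 31)
  an <- analyze_night(nt$recording, nt$hypnogram, nt$artifacts,
                      channels = "F3")
  ev <- an$spindles
  expect_gt(nrow(ev), 3)
  expect_true(all(ev$duration_s >= 0.5 & ev$duration_s <= 3.0))
  expect_true(all(ev$amplitude_uv <= 200))
  expect_true(all(ev$start_s < ev$peak_s & ev$peak_s < ev$end_s))
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(utils::head(ev$end_s, -1) <= ev$start_s[-1]))  # no overlap
})

test_that("spindle density divides count by included minutes", {
  expect_equal(spindle_density(30, 10), 3)
  expect_equal(spindle_density(0, 10), 0)
  expect_error(spindle_density(5, 0), "undefined")
})
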