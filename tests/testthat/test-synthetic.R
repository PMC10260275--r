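test_that("identical spec and seed reproduce the night exactly", {
  spec <- simulation_spec(night_min = 6, channels = c("F3", "A1", "A2"))
  a <- simulate_night(spec, seed = 10)
  b <- simulate_night(spec, seed = 10)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$spindles, b$truth$spindles)
  expect_identical(a$hypnogram$stages, b$hypnogram$stages)
  c_ <- simulate_night(spec, seed = 11)
  expect_false(identical(a$recording$data, c_$recording$data))
})

test_that("realized stage fractions match the spec within 0.03", {
  spec <- simulation_spec(night_min = 60)
  nt <- simulate_night(spec, seed = 12)
  fr <- table(factor(nt$hypnogram$stages,
                     levels = c("W", "N1", "N2", "N3", "REM"))) /
    length(nt$hypnogram$stages)
  expect_lt(abs(fr[["N2"]] - 0.36), 0.03)
  expect_lt(abs(fr[["N3"]] - 0.24), 0.03)
  expect_lt(abs(fr[["REM"]] - 0.18), 0.03)
})

test_that("invalid specs are rejected", {
  expect_error(simulation_spec(stage_frac = c(N1 = 0.5, N2 = 0.4, N3 = 0.3,
                                              REM = 0.2)), "at most 1")
  expect_error(simulation_spec(spindle.freq = c(100, 140), rate = 128),
               "Nyquist")
})

test_that("pink noise has the requested RMS and a falling spectrum", {
  set.seed(13)
  x <- pink_noise(2^15, slope = 1, rms = 15)
  expect_equal(sd(x), 15, tolerance = 1e-6)
  psd <- epoch_psd(x, 128)
  lo <- band_mean(psd, c(1, 4)); hi <- band_mean(psd, c(16, 30))
  expect_gt(lo - hi, 5)   # dB decline across a decade of frequency
})

test_that("von Mises sampling matches its stated moments", {
  set.seed(14)
  x <- rvonmises(3000, 0.8, 5)
  expect_lt(abs(circ_mean(x) - 0.8), 0.05)
  expect_true(all(x > -pi & x <= pi))
  u <- rvonmises(3000, 0, 0)                 # kappa = 0: circular uniform
  expect_gt(rayleigh_test(u)$p_value, 0.01)
  # E|phi| inversion round-trips
  expect_equal(vm_mean_abs_phase(0), pi / 2)
  k <- spindlelat:::kappa_for_distance(0.6)
  expect_equal(vm_mean_abs_phase(k), 0.6, tolerance = 1e-4)
})

test_that("null injection leaves only a small false-positive floor", {
  spec <- simulation_spec(night_min = 12, channels = c("F3", "A1", "A2"),
                          spindle.rate_per_min = 0, so.rate_per_min = 0,
                          artifact.epoch_frac = 0)
  nt <- simulate_night(spec, seed = 15)
  expect_equal(nrow(nt$truth$spindles), 0)
  expect_equal(nrow(nt$truth$sos), 0)
  an <- analyze_night(nt$recording, nt$hypnogram, nt$artifacts,
                      channels = "F3")
  fp_per_min <- nrow(an$spindles) / an$nrem_minutes
  expect_lt(fp_per_min, 0.5)
})

test_that("a right spindle-rate asymmetry yields positive density contrast", {
  diffs <- vapply(1:10, function(seed) {
    spec <- simulation_spec(night_min = 6, channels = c("F3", "F4", "A1", "A2"),
                            so.rate_per_min = 0, artifact.epoch_frac = 0)
    nt <- simulate_night(spec, seed = 300 + seed,
                         lat = list(spindle = 0.2, spindle_central = 0,
                                    coupling = 0, theta = 0))
    tr <- nt$truth$spindles
    sum(tr$channel == "F4") - sum(tr$channel == "F3")
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("response tables honor the task design invariants", {
  spec <- simulation_spec()
  resp <- simulate_responses(spec, seed = 16)
  expect_silent(check_response_table(resp))
  td <- task_design()
  expect_equal(nrow(resp), 3 * (td$n_targets_retrieval + td$n_foils_retrieval))
  expect_equal(td$n_stimuli_total, 300)
})

test_that("cohort bundles carry one night and one response set per subject", {
  spec <- simulation_spec(n_subjects = 3, night_min = 4,
                          channels = c("F3", "A1", "A2"))
  coh <- simulate_cohort(spec, seed = 17, eeg = TRUE)
  expect_length(coh$nights, 3)
  expect_equal(nrow(coh$covariates), 3)
  expect_equal(nrow(coh$responses), 3 * 300)
  expect_true(all(c("coupling_lat_true", "spindle_lat_true") %in%
                    names(coh$covariates)))
  # determinism across calls
  coh2 <- simulate_cohort(spec, seed = 17, eeg = TRUE)
  expect_identical(coh$responses, coh2$responses)
  expect_identical(coh$nights[[2]]$recording$data,
                   coh2$nights[[2]]$recording$data)
})

test_that("score-level and response-level simulations agree in expectation", {
  spec <- simulation_spec()
  sc <- simulate_score_cohort(spec, seed = 18)
  resp_based <- scores_array(score_responses(simulate_cohort(
    spec, seed = 18, eeg = FALSE)$responses))
  # same model, different sampling paths: compare the grand structure
  expect_equal(dim(sc$d_array), dim(resp_based))
  expect_lt(abs(mean(sc$d_array) - mean(resp_based)), 0.25)
})

test_that("wiring weights shift the emotional difference as specified", {
  spec0 <- simulation_spec(wiring.coupling_to_emotion = 0,
                           wiring.spindle_to_emotion_24h = 0,
                           memory.subj_emo_sd = 0)
  set.seed(19)
  p_neutral <- spindlelat:::subject_memory_params(
    spec0, list(coupling = 1, spindle = 1, theta = 0))
  gap0 <- p_neutral$strength["neutral", ] - p_neutral$strength["emotional", ]
  specw <- simulation_spec(wiring.coupling_to_emotion = -0.8,
                           wiring.spindle_to_emotion_24h = 0.8,
                           memory.subj_emo_sd = 0)
  set.seed(19)
  pw <- spindlelat:::subject_memory_params(
    specw, list(coupling = 1, spindle = 1, theta = 0))
  gapw <- pw$strength["neutral", ] - pw$strength["emotional", ]
  expect_equal(unname((gapw - gap0)[1]), -0.8, tolerance = 1e-10)
  expect_equal(unname((gapw - gap0)[3]), -0.8 + 0.8, tolerance = 1e-10)
})
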