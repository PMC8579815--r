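test_that("COV of propagation speed follows the direct formula", {
  expect_identical(cov_propagation_speed(rep(0.25, 7)), 0)
  d <- c(0.2, 0.2, 0.2, 0.4, 0.2, 0.2, 0.2)
  # value frozen from an independent spreadsheet-style evaluation
  expect_equal(cov_propagation_speed(d), 33.071891388307385,
               tolerance = 1e-12)
  expect_equal(cov_propagation_speed(d), oracle_cov(d), tolerance = 1e-12)
  # scale invariance
  set.seed(1)
  for (i in 1:20) {
    dd <- runif(7, 0.1, 0.5)
    k <- runif(1, 0.1, 10)
    expect_equal(cov_propagation_speed(k * dd), cov_propagation_speed(dd),
                 tolerance = 1e-9)
  }
  expect_error(cov_propagation_speed(0.3), "at least two")
  expect_error(cov_propagation_speed(c(-0.1, 0.1)), "zero")
})

test_that("residual amplitude is zero for single-pulse markers and picks up echoes", {
  tr <- generate_trial(clean_spec(seed = 2))
  seg <- segment_wave(tr, select_analysis_window(tr))
  expect_identical(as.numeric(residual_amplitude(seg, tr)), 0)

  # inject a 12 mm echo bump on the left wrist, away from its own pulse
  tr$z[, "wrist_L"] <- tr$z[, "wrist_L"] + hann_lobe(tr$t, 2.7, 12, 0.15)
  seg2 <- segment_wave(tr, select_analysis_window(tr))
  expect_equal(as.numeric(residual_amplitude(seg2, tr)), 12 / 8)
})

test_that("doubling residual motion roughly doubles residual amplitude", {
  mean_resid <- function(rsd, n = 12) {
    mean(vapply(seq_len(n), function(i) {
      tr <- generate_trial(wave_spec(residual_sd = rsd, sensor_noise_sd = 0,
                                     dropout_trial_fraction = 0))
      analyze_trial(tr)$residual_amplitude
    }, numeric(1)))
  }
  set.seed(3)
  r8 <- mean_resid(8)
  r16 <- mean_resid(16)
  expect_gt(r16 / r8, 1.4)
  expect_lt(r16 / r8, 2.8)
})

test_that("the wave/residual ratio divides and flags zero residuals", {
  expect_identical(wave_residual_ratio(100, 10), 10)
  expect_identical(wave_residual_ratio(100, 0), Inf)
  tr <- generate_trial(clean_spec(seed = 4))
  m <- analyze_trial(tr)
  expect_true(m$ratio_flagged)
  expect_identical(m$wave_residual_ratio, Inf)
})

test_that("stationary-markers residual mode needs such markers", {
  tr <- generate_trial(clean_spec(seed = 5))
  seg <- segment_wave(tr, select_analysis_window(tr))
  expect_error(residual_amplitude(seg, tr, mode = "stationary-markers"),
               "no stationary")
  tr2 <- generate_trial(clean_spec(seed = 5, emit_head_marker = TRUE))
  seg2 <- segment_wave(tr2, select_analysis_window(tr2))
  expect_identical(as.numeric(residual_amplitude(seg2, tr2,
                                                 mode = "stationary-markers")),
                   0)
})

test_that("shoulder-to-shoulder interval follows the peak schedule", {
  onsets <- seq(0.5, by = 0.25, length.out = 8)
  tr <- generate_trial(clean_spec(chain_onsets = onsets, seed = 6))
  s2s <- shoulder_to_shoulder(segment_wave(tr, select_analysis_window(tr)))
  expect_equal(unname(s2s["interval"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(s2s["percent"]), 100 / 7, tolerance = 1e-6)

  # a mid-wave pause shows up as the shoulder interval
  lags <- c(0.2, 0.2, 0.2, 0.6, 0.2, 0.2, 0.2)
  onsets2 <- 0.5 + cumsum(c(0, lags))
  tr2 <- generate_trial(clean_spec(chain_onsets = onsets2, seed = 6))
  s2s2 <- shoulder_to_shoulder(segment_wave(tr2, select_analysis_window(tr2)))
  expect_equal(unname(s2s2["interval"]), 0.6, tolerance = 1e-9)

  # symmetric under direction reversal
  spec_rl <- clean_spec(chain_onsets = onsets2, seed = 6)
  spec_rl$direction <- "right-to-left"
  tr3 <- generate_trial(spec_rl)
  s2s3 <- shoulder_to_shoulder(segment_wave(tr3, select_analysis_window(tr3)))
  expect_equal(unname(s2s3["interval"]), unname(s2s2["interval"]),
               tolerance = 1e-9)
})

test_that("clean-trial metrics equal direct evaluation of the definitions", {
  set.seed(7)
  for (i in 1:5) {
    lags <- sample(20:35, 7, replace = TRUE) / 100
    onsets <- 0.45 + cumsum(c(0, lags))
    amps <- runif(8, 40, 150)
    spec <- clean_spec(chain_amplitudes = amps, chain_onsets = onsets,
                       trial_duration = ceiling(max(onsets) + 0.45))
    tr <- generate_trial(spec)
    m <- analyze_trial(tr)
    # independent application of the definitions to the generator truth
    expect_equal(m$wave_amplitude, mean(amps), tolerance = 1e-9)
    expect_equal(m$wrist_minus_shoulder,
                 mean(amps[c(2, 7)]) - mean(amps[c(4, 5)]), tolerance = 1e-9)
    expect_equal(m$wave_duration, onsets[8] - onsets[1], tolerance = 1e-9)
    expect_equal(m$mean_sub_duration, mean(lags), tolerance = 1e-9)
    expect_equal(m$cov_propagation, oracle_cov(lags), tolerance = 1e-6)
    expect_equal(m$shoulder_interval, lags[4], tolerance = 1e-9)
    expect_equal(m$shoulder_interval_pct, 100 * lags[4] / sum(lags),
                 tolerance = 1e-6)
    expect_true(m$valid_order)
  }
})

test_that("metrics are unit-equivariant and time-shift invariant", {
  tr <- generate_trial(clean_spec(seed = 8))
  m0 <- analyze_trial(tr)

  k <- 1.7
  tr_k <- tr
  for (ax in c("x", "y", "z")) tr_k[[ax]] <- tr_k[[ax]] * k
  m_k <- analyze_trial(tr_k)
  expect_equal(m_k$wave_amplitude, k * m0$wave_amplitude, tolerance = 1e-9)
  expect_equal(m_k$wrist_minus_shoulder, k * m0$wrist_minus_shoulder,
               tolerance = 1e-9)
  expect_equal(m_k$cov_propagation, m0$cov_propagation, tolerance = 1e-9)
  expect_equal(m_k$shoulder_interval_pct, m0$shoulder_interval_pct,
               tolerance = 1e-9)
  expect_equal(m_k$wave_duration, m0$wave_duration, tolerance = 1e-9)

  tr_s <- tr
  tr_s$t <- tr_s$t + 5
  m_s <- analyze_trial(tr_s)
  for (v in wave_metric_variables()) {
    expect_equal(m_s[[v]], m0[[v]], tolerance = 1e-9)
  }
})

test_that("unanalyzable trials yield explicit missing fields, not zeros", {
  tr <- generate_trial(clean_spec(seed = 9))
  tr$z[] <- 1100 + tr$x * 0
  m <- analyze_trial(tr)
  expect_false(m$excluded)
  expect_true(is.na(m$wave_amplitude))
  expect_true(is.na(m$cov_propagation))
  expect_match(m$note, "unsegmentable")
})
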