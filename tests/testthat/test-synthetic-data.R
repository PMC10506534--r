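test_that("config validation rejects impossible parameters", {
  expect_error(simulation_config(duration_s = 0), class = "saccadescope_invalid_config")
  expect_error(simulation_config(frame_rate = -30), class = "saccadescope_invalid_config")
  expect_error(simulation_config(burst_prob = 1.2), class = "saccadescope_invalid_config")
  expect_error(neuron_spec("enhanced", noise_sd = 0), class = "saccadescope_invalid_config")
  expect_error(neuron_spec("wiggly"), "arg")
})

test_that("a zero-rate configuration yields a pure fixation trace", {
  cfg <- simulation_config(duration_s = 60, saccade_rate = 0, dropout_rate = 0,
                           fixation_noise_sd = 0.2, rng_seed = 7)
  g <- generate_gaze_trace(cfg)
  expect_equal(nrow(g$trace), 60 * 30)
  expect_equal(nrow(g$ground_truth$saccades), 0)
  # position scatter matches the configured jitter (centre relaxes slowly,
  # so allow a loose band around the nominal SD)
  expect_lt(abs(sd(g$trace$azimuth_deg) - 0.2), 0.1)
})

test_that("identical seeds reproduce traces bitwise; different seeds differ", {
  cfg <- simulation_config(duration_s = 120, rng_seed = 42)
  a <- generate_gaze_trace(cfg)
  b <- generate_gaze_trace(cfg)
  expect_identical(a, b)
  cfg2 <- simulation_config(duration_s = 120, rng_seed = 43)
  expect_false(identical(generate_gaze_trace(cfg2)$trace$azimuth_deg,
                         a$trace$azimuth_deg))
})

test_that("event counts and magnitudes follow the configured distributions", {
  cfg <- simulation_config(duration_s = 600, saccade_rate = 6, rng_seed = 1)
  g <- generate_gaze_trace(cfg)
  n <- nrow(g$ground_truth$saccades)
  expect_gte(n, qpois(0.005, 60))
  expect_lte(n, qpois(0.995, 60))
  # larger sample for distributional checks
  cfg2 <- simulation_config(duration_s = 3600, saccade_rate = 6,
                            dropout_rate = 0, rng_seed = 7)
  s <- generate_gaze_trace(cfg2)$ground_truth$saccades
  nasal <- s$magnitude[s$direction == "nasal"]
  expect_lt(abs(mean(nasal) - 7.10), 3 * 3.19 / sqrt(length(nasal)))
  temporal <- s$magnitude[s$direction == "temporal"]
  expect_lt(abs(mean(temporal) - 6.14), 3 * 2.78 / sqrt(length(temporal)))
  expect_gt(mean(s$direction != "other"), 0.9)
  expect_true(all(s$magnitude >= 0.5))
  # bursty interval structure
  iv <- diff(s$onset_frame) / 30
  expect_lt(abs(mean(iv <= 2) - 0.335), 3 * sqrt(0.335 * 0.665 / length(iv)))
})

test_that("ground-truth saccades are ordered and realized exactly in the trace", {
  cfg <- simulation_config(duration_s = 900, dropout_rate = 0, rng_seed = 3)
  g <- generate_gaze_trace(cfg)
  s <- g$ground_truth$saccades
  expect_true(all(diff(s$onset_frame) > 0))
  expect_true(all(s$offset_frame > s$onset_frame))
  expect_true(all(s$onset_frame[-1] > s$offset_frame[-nrow(s)]))
  for (i in seq_len(nrow(s))) {
    daz <- g$trace$azimuth_deg[s$offset_frame[i] + 1] -
      g$trace$azimuth_deg[s$onset_frame[i] + 1]
    del <- g$trace$elevation_deg[s$offset_frame[i] + 1] -
      g$trace$elevation_deg[s$onset_frame[i] + 1]
    expect_lt(abs(sqrt(daz^2 + del^2) - s$magnitude[i]), 0.1)
  }
})

test_that("dropout marks missing frames at the configured rate", {
  cfg <- simulation_config(duration_s = 600, saccade_rate = 0,
                           dropout_rate = 0.05, rng_seed = 9)
  g <- generate_gaze_trace(cfg)
  n <- nrow(g$trace)
  miss <- sum(is.na(g$trace$azimuth_deg))
  expect_gte(miss, qbinom(0.005, n, 0.05))
  expect_lte(miss, qbinom(0.995, n, 0.05))
  # missingness hits both dimensions together
  expect_identical(is.na(g$trace$azimuth_deg), is.na(g$trace$elevation_deg))
})

test_that("dF/F generator realizes each response archetype", {
  cfg <- simulation_config(duration_s = 1200, saccade_rate = 10,
                           dropout_rate = 0, rng_seed = 11)
  g <- generate_gaze_trace(cfg)
  tr <- g$ground_truth$saccades
  n_frames <- nrow(g$trace)
  specs <- list(neuron_spec("null", noise_sd = 0.01),
                neuron_spec("enhanced", amplitude = 0.2, noise_sd = 1e-9),
                neuron_spec("suppressed", amplitude = 0.2, noise_sd = 1e-9),
                neuron_spec("ds_temporal", amplitude = 0.2, noise_sd = 1e-9))
  dff <- generate_dff(g$ground_truth, specs, n_frames, 30, rng_seed = 5)
  w <- response_windows()
  resp <- per_saccade_responses(dff, tr$onset_frame, w)
  ok <- !is.na(resp[1, ])
  # null neuron: event-triggered mean indistinguishable from zero
  m_null <- mean(resp[1, ok])
  se <- sd(resp[1, ok]) / sqrt(sum(ok))
  expect_lt(abs(m_null), 3 * se)
  # noiseless enhanced: strictly positive at every saccade
  expect_true(all(resp[2, ok] > 0))
  # suppressed mirrors enhanced
  expect_equal(resp[3, ok], -resp[2, ok], tolerance = 1e-6)
  # ds_temporal: temporal responses exceed nasal in expectation
  t_resp <- resp[4, ok & tr$direction == "temporal"]
  n_resp <- resp[4, ok & tr$direction == "nasal"]
  expect_gt(mean(t_resp), mean(n_resp))
  expect_gt(length(t_resp) + length(n_resp), 100)
})

test_that("dF/F generator enforces its preconditions", {
  gt <- list(saccades = data.frame(onset_frame = 10L, offset_frame = 12L,
                                   direction = "nasal"))
  expect_error(generate_dff(gt, list(), 100, 30), class = "saccadescope_invalid_input")
  expect_error(generate_dff(gt, list(neuron_spec("null")), 5, 30),
               class = "saccadescope_invalid_input")
  expect_error(generate_dff(gt, list(neuron_spec("null")), 100, 30,
                            saccade_gain = c(1, 1)),
               class = "saccadescope_invalid_input")
})

test_that("stimulus epochs partition the frame axis exactly", {
  # single epoch spanning the session
  one <- generate_stimulus_epochs(data.frame(stimulus = "S", duration = 300), 300)
  expect_equal(nrow(one), 1)
  expect_equal(one$start_frame, 0)
  expect_equal(one$end_frame, 300)
  # 50/50 split
  two <- generate_stimulus_epochs(
    data.frame(stimulus = c("DG", "S"), duration = c(150, 150)), 300)
  expect_equal(two$start_frame, c(0, 150))
  # eight-stimulus template: exhaustive frame scan finds exactly one epoch
  # per frame
  tpl <- default_session_template(1000)
  ep <- generate_stimulus_epochs(tpl, 1000)
  cover <- integer(1000)
  for (i in seq_len(nrow(ep))) {
    idx <- (ep$start_frame[i] + 1):ep$end_frame[i]
    cover[idx] <- cover[idx] + 1L
  }
  expect_true(all(cover == 1L))
  expect_error(generate_stimulus_epochs(
    data.frame(stimulus = "S", duration = 301), 300),
    class = "saccadescope_invalid_input")
})
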