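make_trace <- function(az, el = rep(0, length(az)), fr = 30) {
  gaze_trace(az, el, fr)
}

test_that("speed profile applies the floor and handles missing frames", {
  tr <- make_trace(rep(1, 100))
  p <- compute_speed(tr)
  expect_true(all(p$speed == 0))
  expect_equal(p$mu, 0)
  expect_equal(p$sigma, 0)
  expect_equal(p$outlier_threshold, 10)
  # a single 1-degree step at 30 Hz is 30 deg/s
  az <- rep(0, 50); az[26:50] <- 1
  p2 <- compute_speed(make_trace(az))
  expect_equal(p2$speed[25], 30)
  expect_equal(sum(p2$speed > 0), 1)
  # a missing frame k kills the two adjacent speed intervals, and the
  # statistics match a direct recomputation over the remainder
  az3 <- sin(seq(0, 4, length.out = 60))
  az3[20] <- NA
  p3 <- compute_speed(make_trace(az3))
  expect_true(is.na(p3$speed[19]))  # interval (18,19) 0-based
  expect_true(is.na(p3$speed[20]))
  brute <- sqrt(diff(az3)^2) * 30
  expect_equal(p3$mu, mean(brute, na.rm = TRUE))
  expect_equal(p3$sigma, sd(brute, na.rm = TRUE))
  expect_error(compute_speed(make_trace(rep(NA_real_, 10))),
               class = "saccadescope_invalid_input")
})

test_that("candidate detection matches the brute-force two-threshold oracle", {
  # the printed mini-trace: threshold arithmetic leaves no outlier frame
  sp <- c(0, 2, 12, 30, 12, 2, 0)
  mu <- mean(sp); sig <- sd(sp)
  prof <- structure(list(speed = sp, mu = mu, sigma = sig,
                         outlier_threshold = max(mu + 3 * sig, 10),
                         extension_threshold = mu + sig,
                         frame_rate = 30, n_frames = 8),
                    class = "speed_profile")
  got <- detect_candidates(prof)
  want <- oracle_candidates(sp, prof$outlier_threshold, prof$extension_threshold)
  expect_equal(got, want)
  # one isolated outlier over a zero baseline
  sp2 <- rep(0, 20); sp2[10] <- 50
  prof2 <- structure(list(speed = sp2, mu = mean(sp2), sigma = sd(sp2),
                          outlier_threshold = 10,
                          extension_threshold = mean(sp2) + sd(sp2),
                          frame_rate = 30, n_frames = 21),
                     class = "speed_profile")
  got2 <- detect_candidates(prof2)
  expect_equal(nrow(got2), 1)
  expect_true(got2$onset_frame <= 9 && got2$offset_frame >= 10)
  # randomized traces, including NA gaps: exact agreement with the oracle
  set.seed(5)
  for (rep in 1:25) {
    sp3 <- abs(rnorm(200, 4, 3)) + ifelse(runif(200) < 0.05, 60, 0)
    sp3[sample(200, 5)] <- NA
    out_thr <- max(mean(sp3, na.rm = TRUE) + 3 * sd(sp3, na.rm = TRUE), 10)
    ext_thr <- mean(sp3, na.rm = TRUE) + sd(sp3, na.rm = TRUE)
    prof3 <- structure(list(speed = sp3, mu = mean(sp3, na.rm = TRUE),
                            sigma = sd(sp3, na.rm = TRUE),
                            outlier_threshold = out_thr,
                            extension_threshold = ext_thr,
                            frame_rate = 30, n_frames = 201),
                       class = "speed_profile")
    expect_equal(detect_candidates(prof3), oracle_candidates(sp3, out_thr, ext_thr))
  }
})

test_that("every detected event obeys the two-threshold invariant", {
  cfg <- simulation_config(duration_s = 300, fixation_noise_sd = 0.3,
                           dropout_rate = 0, rng_seed = 21)
  g <- generate_gaze_trace(cfg)
  prof <- compute_speed(g$trace)
  ev <- detect_saccades(g$trace)
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev))) {
    idx <- (ev$onset_frame[i] + 1):ev$offset_frame[i]  # speed intervals
    expect_true(any(prof$speed[idx] > prof$outlier_threshold))
    expect_true(all(prof$speed[idx] > prof$extension_threshold))
  }
})

test_that("validation compares displacement against flanking noise", {
  # clean 8-degree azimuth step: zero noise floor accepts any displacement
  az <- c(rep(0, 20), 4, rep(8, 20))
  v <- validate_saccade(make_trace(az), 19, 21)
  expect_true(v$valid)
  expect_equal(unname(v$context$delta[1]), 8)
  # a missing frame in the pre-window invalidates
  az2 <- az; az2[15] <- NA
  expect_false(validate_saccade(make_trace(az2), 19, 21)$valid)
  # windows extending outside the trace invalidate
  expect_false(validate_saccade(make_trace(az), 3, 21)$valid)
  # jitter-only candidate: a 0.3-degree step inside ~0.5-degree noise is
  # rejected (0.3 < 3 x max sd). Windows built deterministically.
  azj <- rep(0, 60)
  azj[21:29] <- rep(c(0.5, -0.5), length.out = 9)   # pre-window, sd ~ 0.53
  azj[30:32] <- c(0, 0.15, 0.3)                     # candidate frames
  azj[33:41] <- 0.3 + rep(c(0.5, -0.5), length.out = 9)  # post-window
  vj <- validate_saccade(make_trace(azj), 29, 31)
  sd_b <- sd(azj[21:29])
  sd_a <- sd(azj[33:41])
  expect_equal(unname(vj$context$threshold[1]), 3 * max(sd_b, sd_a))
  expect_equal(unname(vj$context$delta[1]), 0.3)
  expect_false(vj$valid)
})

test_that("direction sectors partition displacements as printed", {
  expect_equal(classify_direction(5, 0), "temporal")
  expect_equal(classify_direction(-5, 0), "nasal")
  expect_equal(classify_direction(0, 5), "other")
  expect_equal(classify_direction(0, -5), "other")
  # half-open boundaries: exactly 45 degrees is "other"
  expect_equal(classify_direction(1, 1), "other")
  expect_equal(classify_direction(-1, -1), "other")  # 225 falls outside [135, 225)
  expect_error(classify_direction(0, 0), class = "saccadescope_invalid_input")
  # brute-force sector check over random displacements
  set.seed(13)
  for (i in 1:200) {
    d <- rnorm(2)
    ang <- (atan2(d[2], d[1]) * 180 / pi) %% 360
    want <- if (ang >= 315 || ang < 45) "temporal"
            else if (ang >= 135 && ang < 225) "nasal" else "other"
    expect_equal(classify_direction(d[1], d[2]), want)
  }
})

test_that("detector recovers injected saccades and labels their stimulus", {
  cfg <- simulation_config(duration_s = 300, saccade_rate = 2,
                           fixation_noise_sd = 0.02, dropout_rate = 0,
                           rng_seed = 5)
  g <- generate_gaze_trace(cfg)
  truth <- g$ground_truth$saccades
  truth_big <- truth[truth$magnitude >= 3, ]
  ep <- generate_stimulus_epochs(default_session_template(nrow(g$trace)),
                                 nrow(g$trace))
  ev <- detect_saccades(g$trace, ep)
  # every injected saccade >= 3 degrees is found within one frame
  for (o in truth_big$onset_frame) {
    expect_true(any(abs(ev$onset_frame - o) <= 1))
  }
  # no events besides the injected ones
  for (o in ev$onset_frame) {
    expect_true(any(abs(truth$onset_frame - o) <= 2))
  }
  expect_true(all(ev$stimulus %in% ep$stimulus))
  expect_true(all(diff(ev$onset_frame) > 0))
  # without epochs events are unlabeled; an all-missing trace gives nothing
  ev2 <- detect_saccades(g$trace, NULL)
  expect_true(all(ev2$stimulus == "unlabeled"))
  empty <- detect_saccades(gaze_trace(rep(NA_real_, 100), rep(NA_real_, 100), 30))
  expect_equal(nrow(empty), 0)
  # direction labels agree with ground truth at matched onsets
  m <- merge(ev, truth, by = "onset_frame", suffixes = c("", ".t"))
  expect_gt(nrow(m), 0)
  expect_true(all(m$direction == m$direction.t))
})

test_that("steady-gaze filter enforces the quiet period", {
  fr <- 30
  ev <- data.frame(onset_frame = c(0, 30, 150), offset_frame = c(3, 33, 153))
  kept <- steady_gaze_filter(ev, fr, 2)
  expect_equal(kept$onset_frame, 150)
  single <- data.frame(onset_frame = 300, offset_frame = 303)
  expect_equal(nrow(steady_gaze_filter(single, fr, 2)), 1)
  none <- data.frame(onset_frame = integer(0), offset_frame = integer(0))
  expect_equal(nrow(steady_gaze_filter(none, fr, 2)), 0)
})
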