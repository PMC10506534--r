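test_that("saccade response is the response-window minus deep-baseline mean", {
  w <- response_windows()
  expect_equal(saccade_response(rep(2, 200), 100, w), 0)
  tr <- rep(0, 200); tr[101:111] <- 1  # frames 100-110, 0-based
  expect_equal(saccade_response(tr, 100, w), 1)
  # linear ramp: closed-form window means
  ramp <- (0:199) / 30
  got <- saccade_response(ramp, 100, w)
  expect_equal(got, mean(ramp[101:111]) - mean(ramp[56:86]))
  expect_equal(got, (105 - 70) / 30)
  # out-of-bounds windows are skip markers
  expect_true(is.na(saccade_response(ramp, 10, w)))
  expect_true(is.na(saccade_response(ramp, 195, w)))
  # matrix form agrees with the scalar form
  dff <- rbind(ramp, rep(2, 200))
  m <- per_saccade_responses(dff, c(10L, 100L), w)
  expect_true(all(is.na(m[, 1])))
  expect_equal(m[, 2], c(got, 0), ignore_attr = TRUE)
})

test_that("bootstrap null matches the exhaustive per-frame distribution", {
  w <- response_windows()
  set.seed(1)
  # only 11 admissible onset frames: every sample must be one of their
  # responses, with near-uniform frequencies
  tr <- rnorm(66)
  support <- vapply(45:55, function(o) saccade_response(tr, o, w), numeric(1))
  null <- build_bootstrap_null(list(tr), 5, w, n_samples = 4000, seed = 2)
  nearest <- vapply(null$samples, function(v) which.min(abs(v - support)),
                    integer(1))
  expect_lt(max(abs(null$samples - support[nearest])), 1e-12)
  freq <- tabulate(nearest, nbins = 11)
  expect_true(all(freq > 4000 / 11 - 5 * sqrt(4000 * (1 / 11) * (10 / 11))))
  expect_equal(null$weights, 1)
  # white-noise null is centred at zero
  tr2 <- rnorm(6000)
  null2 <- build_bootstrap_null(list(tr2), 10, w, n_samples = 20000, seed = 3)
  expect_lt(abs(mean(null2$samples)), 0.03)
  # two sessions weighted by saccade counts; a linear ramp shifts every
  # response of the second session by slope x window separation (35)
  nullw <- build_bootstrap_null(list(tr2, tr2 + seq_len(6000)), c(30, 10), w,
                                n_samples = 10000, seed = 4)
  frac_hi <- mean(nullw$samples > 20)
  expect_lt(abs(frac_hi - 0.25), 5 * sqrt(0.25 * 0.75 / 10000))
  expect_error(build_bootstrap_null(list(rnorm(20)), 5, w, 100, 1),
               class = "saccadescope_null_construction")
})

test_that("tail-quantile classification uses mid-rank ties", {
  null <- 1:99
  expect_equal(classify_sr(50, null)$q, 0.5)
  expect_equal(classify_sr(50, null)$class, "none")
  expect_equal(classify_sr(1000, null)$class, "enhanced")
  expect_equal(classify_sr(1000, null)$q, 1)
  expect_equal(classify_sr(-5, null)$class, "suppressed")
  # mid-rank: observed equal to every null sample sits at q = 0.5
  expect_equal(classify_sr(3, rep(3, 10))$q, 0.5)
  expect_error(classify_sr(1, numeric(0)), class = "saccadescope_invalid_input")
  # the printed false-positive arithmetic
  expect_equal(expected_false_positives(32442, 5e-4), 16.221)
})

test_that("direction selectivity follows the enhanced-plus-ranksum rule", {
  # T = N: dsi 0 and never DS
  res <- classify_ds(rep(0.2, 20), rep(0.2, 20), "enhanced")
  expect_equal(res$saccade_dsi, 0)
  expect_false(res$ds)
  expect_equal(res$preferred_direction, "none")
  # N = 0, T > 0: dsi 1
  expect_equal(classify_ds(rep(0.3, 5), rep(0, 5), "enhanced")$saccade_dsi, 1)
  # group means from a strongly temporal-preferring population
  res2 <- classify_ds(0.0490, 0.0015, "enhanced")
  expect_equal(res2$saccade_dsi, 0.0475 / 0.0505)
  expect_equal(round(res2$saccade_dsi, 4), 0.9406)
  # clearly separated groups on an enhanced neuron are DS with the right
  # preference; the same data on a suppressed neuron are not DS
  set.seed(4)
  tt <- rnorm(25, 0.3, 0.01); nn <- rnorm(25, 0.01, 0.01)
  ds <- classify_ds(tt, nn, "enhanced")
  expect_true(ds$ds)
  expect_equal(ds$preferred_direction, "temporal")
  expect_false(classify_ds(tt, nn, "suppressed")$ds)
  expect_false(classify_ds(tt, nn, "none")$ds)
  # antisymmetry under swapping directions
  ds_sw <- classify_ds(nn, tt, "enhanced")
  expect_equal(ds_sw$saccade_dsi, -ds$saccade_dsi)
  expect_equal(ds_sw$preferred_direction, "nasal")
  # undefined dsi when T + N = 0
  expect_true(is.na(classify_ds(0.1, -0.1, "enhanced")$saccade_dsi))
})

test_that("container inclusion applies the direction minima", {
  ev <- function(n_nasal, n_temporal) {
    data.frame(direction = c(rep("nasal", n_nasal), rep("temporal", n_temporal)))
  }
  expect_true(container_inclusion(ev(15, 15)))
  expect_false(container_inclusion(ev(14, 100)))
  expect_false(container_inclusion(ev(100, 14)))
  expect_false(container_inclusion(ev(0, 0)))
  expect_true(container_inclusion(ev(3, 3), min_nasal = 3, min_temporal = 3))
})

test_that("modulation tests saturate on strong effects and BH flags control", {
  w <- response_windows()
  set.seed(6)
  n_frames <- 6000
  onsets <- seq(100, 5900, by = 100)
  tr <- rnorm(n_frames, 0, 1e-6)
  for (o in onsets) tr[(o + 1):(o + 11)] <- tr[(o + 1):(o + 11)] + 0.5
  ev <- data.frame(onset_frame = onsets, direction = rep(c("nasal", "temporal"),
                                                         length.out = length(onsets)))
  mt <- modulation_tests(tr, ev, w)
  expect_lt(mt$p_signed_rank, 1e-6)
  expect_gt(mt$p_rank_sum, 0.05)  # direction-symmetric response
  # all-zero paired differences: p missing
  mt0 <- modulation_tests(rep(1, n_frames), ev, w)
  expect_true(is.na(mt0$p_signed_rank))
  # one-direction-only events: rank-sum missing
  ev1 <- transform(ev, direction = "nasal")
  expect_true(is.na(modulation_tests(tr, ev1, w)$p_rank_sum))
  # the BH step on a small printed example at FDR 10%
  flags <- modulation_flags(data.frame(p_signed_rank = c(0.001, 0.02, 0.9),
                                       p_rank_sum = NA_real_), fdr = 0.10)
  expect_equal(flags$p_signed_rank_adj, p.adjust(c(0.001, 0.02, 0.9), "BH"))
  expect_equal(flags$modulated, c(TRUE, TRUE, FALSE))
})

test_that("container classification recovers enhanced and suppressed neurons", {
  classes <- c(rep("enhanced", 6), rep("suppressed", 4), rep("null", 10))
  ses <- make_truth_session(classes, duration_s = 3600, saccade_rate = 0.7,
                            seed = 31)
  cls <- classify_neurons(list(ses), n_boot = 10000, seed = 9)
  expect_true(attr(cls, "included"))
  rec <- recovered_class(cls)
  expect_gte(mean(rec[1:10] == classes[1:10]), 0.9)
  # null neurons essentially never flagged (observed mean is an average of
  # many draws, far more central than single null samples)
  expect_true(all(rec[11:20] == "null"))
  expect_true(all(cls$q >= 0 & cls$q <= 1))
  expect_true(all(cls$class %in% c("enhanced", "suppressed", "none")))
  # DS flags only on enhanced neurons
  expect_true(all(!cls$ds | cls$class == "enhanced"))
})

test_that("classification skips containers below the saccade minima", {
  classes <- c("enhanced", "null")
  ses <- make_truth_session(classes, duration_s = 600, saccade_rate = 0.5,
                            seed = 11)
  cls <- classify_neurons(list(ses), n_boot = 500, seed = 2)
  expect_false(attr(cls, "included"))
  expect_true(all(is.na(cls$class)))
})

test_that("spontaneous-only variant restricts saccades and null frames", {
  n_frames <- 108000
  half <- data.frame(stimulus = c("DG", "S"),
                     start_frame = c(0L, n_frames / 2L),
                     end_frame = c(n_frames / 2L, n_frames))
  classes <- c("enhanced", "null")
  ses <- make_truth_session(classes, duration_s = 3600, saccade_rate = 0.7,
                            seed = 51, epochs = half)
  # enhanced neuron responds during all stimuli: flagged by both variants
  std <- classify_neurons(list(ses), n_boot = 8000, seed = 3)
  spont <- classify_neurons(list(ses), n_boot = 8000, seed = 3,
                            spontaneous_only = TRUE)
  expect_true(attr(spont, "included"))
  expect_equal(std$class[1], "enhanced")
  expect_equal(spont$class[1], "enhanced")
  expect_equal(std$class[2], "none")
  expect_equal(spont$class[2], "none")
  # fewer saccades enter the spontaneous variant
  expect_lt(spont$n_saccades[1], std$n_saccades[1])
  # below the 3/3 spontaneous minimum the container is excluded
  few <- ses
  keep <- few$events$stimulus != "S" |
    seq_len(nrow(few$events)) %in% head(which(few$events$stimulus == "S"), 2)
  few$events <- few$events[keep, , drop = FALSE]
  spont2 <- classify_neurons(list(few), n_boot = 500, seed = 3,
                             spontaneous_only = TRUE)
  expect_false(attr(spont2, "included"))
})

test_that("stimulus-conditioned responses normalise against spontaneous", {
  w <- response_windows()
  n_frames <- 54000
  half <- data.frame(stimulus = c("NM-1", "S"),
                     start_frame = c(0L, n_frames / 2L),
                     end_frame = c(n_frames / 2L, n_frames))
  ses <- make_truth_session(rep("enhanced", 4), duration_s = 1800,
                            saccade_rate = 1.2, seed = 61, epochs = half,
                            noise_sd = 1e-6, kernel_tau = 0.2)
  cl <- data.frame(class = "enhanced", ds = FALSE,
                   preferred_direction = "none")[rep(1, 4), ]
  res <- stimulus_conditioned_responses(list(ses), cl, w)
  # identical response statistics during both stimuli: ratios ~1
  expect_true(all(abs(res$per_neuron$ratio - 1) < 0.05))
  # sessions below the spontaneous minimum are rejected
  few <- ses
  keep <- few$events$stimulus != "S" |
    seq_len(nrow(few$events)) %in% head(which(few$events$stimulus == "S"), 7)
  few$events <- few$events[keep, , drop = FALSE]
  expect_error(stimulus_conditioned_responses(list(few), cl, w),
               class = "saccadescope_invalid_input")
})
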