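# Shared builders and independent oracles for the test suite.

# Build an analysis session (dff + ground-truth events + epochs) without
# going through saccade detection, so classifier tests are isolated from
# the detector. `classes` gives one true class per neuron.
make_truth_session <- function(classes, duration_s = 3600, saccade_rate = 0.7,
                               seed = 1, amplitude = 0.25, noise_sd = 0.02,
                               kernel_tau = 0.5, epochs = NULL,
                               saccade_gain = NULL, frame_rate = 30) {
  cfg <- simulation_config(duration_s = duration_s, frame_rate = frame_rate,
                           saccade_rate = saccade_rate, burst_prob = 0,
                           dropout_rate = 0, rng_seed = seed)
  g <- generate_gaze_trace(cfg)
  n_frames <- nrow(g$trace)
  if (is.null(epochs)) {
    epochs <- data.frame(stimulus = "S", start_frame = 0L,
                         end_frame = n_frames)
  }
  tr <- g$ground_truth$saccades
  specs <- lapply(classes, function(cl) {
    neuron_spec(cl, amplitude = amplitude, noise_sd = noise_sd,
                kernel_tau = kernel_tau)
  })
  if (is.function(saccade_gain)) saccade_gain <- saccade_gain(tr, epochs)
  dff <- generate_dff(g$ground_truth, specs, n_frames, frame_rate,
                      rng_seed = seed + 5000, saccade_gain = saccade_gain)
  events <- data.frame(
    onset_frame = tr$onset_frame, offset_frame = tr$offset_frame,
    direction = tr$direction, magnitude = tr$magnitude,
    stimulus = epoch_label_for_test(tr$onset_frame, epochs),
    stringsAsFactors = FALSE)
  list(dff = dff, events = events, epochs = epochs, truth = tr)
}

epoch_label_for_test <- function(frames, epochs) {
  vapply(frames, function(f) {
    hit <- which(epochs$start_frame <= f & f < epochs$end_frame)
    if (length(hit) == 0) "unlabeled" else epochs$stimulus[hit[1]]
  }, character(1))
}

# Brute-force two-threshold candidate scan: for every interval above the
# outlier threshold, expand left and right while above the extension
# threshold; de-duplicate. Independent of the rle-based implementation.
oracle_candidates <- function(speed, out_thr, ext_thr) {
  n <- length(speed)
  above_ext <- !is.na(speed) & speed > ext_thr
  seen <- list()
  for (i in seq_len(n)) {
    if (!is.na(speed[i]) && speed[i] > out_thr) {
      lo <- i
      while (lo > 1 && above_ext[lo - 1]) lo <- lo - 1
      hi <- i
      while (hi < n && above_ext[hi + 1]) hi <- hi + 1
      seen[[paste(lo, hi)]] <- c(lo, hi)
    }
  }
  if (length(seen) == 0) {
    return(data.frame(onset_frame = integer(0), offset_frame = integer(0)))
  }
  m <- do.call(rbind, seen)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- data.frame(onset_frame = m[, 1] - 1L, offset_frame = m[, 2])
  rownames(out) <- NULL
  out
}

# Numeric specular-reflection oracle: the glint is the point on the eye
# sphere where the incoming ray from the (distant) LED reflects into the
# (distant) camera direction. Searches the great circle spanned by the two
# directions, which contains the solution by symmetry.
oracle_reflection <- function(led_dir, cam_dir, radius) {
  u <- led_dir / sqrt(sum(led_dir^2))
  v <- cam_dir / sqrt(sum(cam_dir^2))
  w <- v - sum(v * u) * u
  if (sqrt(sum(w^2)) < 1e-12) return(radius * u)  # coaxial
  w <- w / sqrt(sum(w^2))
  loss <- function(th) {
    nrm <- cos(th) * u + sin(th) * w
    refl <- -u - 2 * sum(-u * nrm) * nrm  # reflect incoming direction -u
    sum((refl - v)^2)
  }
  th <- stats::optimize(loss, c(-pi / 2, pi / 2), tol = 1e-12)$minimum
  radius * (cos(th) * u + sin(th) * w)
}
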