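# Synthetic session generator: gaze traces with ground-truth saccades,
# stimulus epoch tables, and dF/F matrices with known neuron response
# classes. Everything downstream of the raw-data adapters can be exercised
# against these objects with exact ground truth.

#' Simulation configuration for synthetic gaze traces
#'
#' Bundles the parameters of the synthetic eye-movement generator. Defaults
#' reproduce the saccade statistics of head-fixed mice on a visual-coding
#' rig: nasal saccades of 7.10 +/- 3.19 degrees, temporal saccades of
#' 6.14 +/- 2.78 degrees, 96.6% of saccades within 45 degrees of horizontal,
#' and roughly a third of intersaccade intervals at most 2 s (bursting).
#'
#' @param duration_s session duration in seconds.
#' @param frame_rate eye-tracking frame rate in Hz (default 30).
#' @param saccade_rate mean saccade rate in events per minute.
#' @param burst_prob probability that a saccade is followed by another
#'   within 2 s (drives the bursty interval distribution).
#' @param nasal_mag_mean,nasal_mag_sd nasal saccade magnitude distribution
#'   (degrees; Gaussian truncated below at 0.5).
#' @param temporal_mag_mean,temporal_mag_sd temporal saccade magnitude
#'   distribution (degrees; same truncation).
#' @param frac_horizontal probability that a saccade is horizontal
#'   (temporal or nasal) rather than dorsal/ventral.
#' @param prob_nasal probability that a horizontal saccade is nasal
#'   (default 0.533, the nasal share among horizontal saccades).
#' @param fixation_noise_sd per-frame Gaussian jitter of fixation positions
#'   (degrees).
#' @param dropout_rate probability that a frame is missing (failed eye
#'   tracking), applied independently per frame.
#' @param rng_seed integer seed; identical seeds give bitwise-identical
#'   sessions.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 600,
                              frame_rate = 30,
                              saccade_rate = 6,
                              burst_prob = 0.335,
                              nasal_mag_mean = 7.10, nasal_mag_sd = 3.19,
                              temporal_mag_mean = 6.14, temporal_mag_sd = 2.78,
                              frac_horizontal = 0.966,
                              prob_nasal = 0.533,
                              fixation_noise_sd = 0.08,
                              dropout_rate = 0.02,
                              rng_seed = NULL) {
  if (!is_pos_scalar(duration_s)) stop_invalid_config("duration_s must be > 0")
  if (!is_pos_scalar(frame_rate)) stop_invalid_config("frame_rate must be > 0")
  if (!(is.numeric(saccade_rate) && saccade_rate >= 0)) {
    stop_invalid_config("saccade_rate must be >= 0")
  }
  for (p in c(burst_prob = burst_prob, frac_horizontal = frac_horizontal,
              prob_nasal = prob_nasal, dropout_rate = dropout_rate)) {
    if (!is_prob(p)) stop_invalid_config("probabilities must lie in [0, 1]")
  }
  if (!(is.numeric(fixation_noise_sd) && fixation_noise_sd >= 0)) {
    stop_invalid_config("fixation_noise_sd must be >= 0")
  }
  for (m in c(nasal_mag_mean, nasal_mag_sd, temporal_mag_mean, temporal_mag_sd)) {
    if (!is_pos_scalar(m)) stop_invalid_config("magnitude parameters must be > 0")
  }
  structure(list(
    duration_s = duration_s, frame_rate = frame_rate,
    saccade_rate = saccade_rate, burst_prob = burst_prob,
    nasal_mag_mean = nasal_mag_mean, nasal_mag_sd = nasal_mag_sd,
    temporal_mag_mean = temporal_mag_mean, temporal_mag_sd = temporal_mag_sd,
    frac_horizontal = frac_horizontal, prob_nasal = prob_nasal,
    fixation_noise_sd = fixation_noise_sd, dropout_rate = dropout_rate,
    rng_seed = rng_seed
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:", x$duration_s, "s at", x$frame_rate, "Hz;",
      x$saccade_rate, "saccades/min; seed",
      if (is.null(x$rng_seed)) "<none>" else x$rng_seed, "\n")
  invisible(x)
}

#' Per-neuron specification for the dF/F generator
#'
#' @param true_class one of `"enhanced"`, `"suppressed"`, `"ds_nasal"`,
#'   `"ds_temporal"`, `"null"`. Direction-selective classes respond only to
#'   saccades of the matching direction; suppressed neurons carry a
#'   negative-going transient; null neurons receive no event term.
#' @param amplitude transient amplitude in dF/F units (>= 0).
#' @param kernel_tau calcium decay time constant in seconds (> 0).
#' @param noise_sd Gaussian noise SD in dF/F units (> 0).
#' @param baseline constant baseline dF/F.
#' @return An object of class `neuron_spec`.
#' @export
neuron_spec <- function(true_class = c("enhanced", "suppressed", "ds_nasal",
                                       "ds_temporal", "null"),
                        amplitude = 0.25, kernel_tau = 0.5,
                        noise_sd = 0.02, baseline = 0) {
  true_class <- match.arg(true_class)
  if (!(is.numeric(amplitude) && length(amplitude) == 1L && amplitude >= 0)) {
    stop_invalid_config("amplitude must be >= 0")
  }
  if (!is_pos_scalar(kernel_tau)) stop_invalid_config("kernel_tau must be > 0")
  if (!is_pos_scalar(noise_sd)) stop_invalid_config("noise_sd must be > 0")
  structure(list(true_class = true_class, amplitude = amplitude,
                 kernel_tau = kernel_tau, noise_sd = noise_sd,
                 baseline = baseline),
            class = "neuron_spec")
}

# Truncated-normal magnitude draw: redrawn until above the floor, so the
# realized distribution is Normal(mean, sd) conditioned on >= 0.5 degrees.
draw_magnitude <- function(n, mean, sd, floor = 0.5) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < floor)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < floor]
  }
  out
}

# Draw intersaccade intervals (seconds): a burst interval (uniform on
# [0.35, 2] s) with probability burst_prob, otherwise 2 s plus an
# exponential tail whose rate is chosen so the overall mean interval equals
# 60 / saccade_rate.
draw_intervals <- function(n, saccade_rate, burst_prob) {
  target_mean <- 60 / saccade_rate
  short_mean <- (0.35 + 2) / 2
  long_mean <- if (burst_prob < 1) {
    max((target_mean - burst_prob * short_mean) / (1 - burst_prob) - 2, 0.05)
  } else 0.05
  is_burst <- stats::runif(n) < burst_prob
  ivl <- numeric(n)
  ivl[is_burst] <- stats::runif(sum(is_burst), 0.35, 2)
  ivl[!is_burst] <- 2 + stats::rexp(sum(!is_burst), rate = 1 / long_mean)
  ivl
}

# Saccade displacement angle (degrees, CCW from +azimuth/temporal) for a
# direction label. Horizontal sectors are sampled away from the 45-degree
# boundaries so the realized displacement always classifies as drawn.
draw_angle <- function(direction) {
  switch(direction,
    temporal = stats::runif(1, -40, 40) %% 360,
    nasal    = stats::runif(1, 140, 220),
    other    = if (stats::runif(1) < 0.5) stats::runif(1, 50, 130)
               else stats::runif(1, 230, 310)
  )
}

#' Generate a synthetic gaze trace with known saccades
#'
#' Simulates an angular eye-position trace (azimuth, elevation in degrees)
#' at the configured frame rate. Saccade onsets follow a bursty renewal
#' process; each saccade is realized as a 3-frame linear displacement of
#' the drawn magnitude along the drawn direction; fixations between
#' saccades are jittered with Gaussian noise and relax slowly toward the
#' central position so the trace stays on-monitor; dropout frames are set
#' to `NA` in both dimensions.
#'
#' @param config a [simulation_config()].
#' @return A list with components:
#'   \describe{
#'     \item{trace}{a `gaze_trace` data frame: `frame` (0-based),
#'       `azimuth_deg`, `elevation_deg`, with a `frame_rate` attribute.}
#'     \item{ground_truth}{a list with `saccades` (data frame:
#'       `onset_frame`, `offset_frame`, `direction`, `magnitude`,
#'       `angle_deg`) and the `config` used.}
#'   }
#' @export
generate_gaze_trace <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_invalid_config("config must be a simulation_config")
  }
  local_seed(config$rng_seed, {
    fr <- config$frame_rate
    n_frames <- round(config$duration_s * fr)
    # Small saccades complete within one inter-frame interval at 30 Hz
    # (mouse saccades last 10-40 ms); larger ones span two intervals.
    # The realized event therefore covers 2-3 frames, monotone.
    max_sacc_frames <- 2L

    # Event times: renewal process, first onset offset from the session
    # start by one full interval so early events still have context.
    onsets_s <- numeric(0)
    if (config$saccade_rate > 0) {
      t <- 0
      repeat {
        t <- t + draw_intervals(1, config$saccade_rate, config$burst_prob)
        if (t >= config$duration_s - (max_sacc_frames + 2) / fr) break
        onsets_s <- c(onsets_s, t)
      }
    }
    onset_frames <- as.integer(round(onsets_s * fr))
    if (length(onset_frames) > 1) {
      # enforce strict ordering / non-overlap after rounding
      onset_frames <- onset_frames[c(TRUE, diff(onset_frames) > max_sacc_frames)]
    }
    n_sacc <- length(onset_frames)

    direction <- character(n_sacc)
    magnitude <- numeric(n_sacc)
    angle <- numeric(n_sacc)
    if (n_sacc > 0) {
      horiz <- stats::runif(n_sacc) < config$frac_horizontal
      nasal <- stats::runif(n_sacc) < config$prob_nasal
      direction <- ifelse(horiz, ifelse(nasal, "nasal", "temporal"), "other")
      for (i in seq_len(n_sacc)) {
        magnitude[i] <- switch(direction[i],
          nasal    = draw_magnitude(1, config$nasal_mag_mean, config$nasal_mag_sd),
          temporal = draw_magnitude(1, config$temporal_mag_mean, config$temporal_mag_sd),
          other    = draw_magnitude(1,
            (config$nasal_mag_mean + config$temporal_mag_mean) / 2,
            (config$nasal_mag_sd + config$temporal_mag_sd) / 2)
        )
        angle[i] <- draw_angle(direction[i])
      }
    }

    az <- numeric(n_frames)
    el <- numeric(n_frames)
    fix_az <- 0
    fix_el <- 0
    next_sacc <- 1L
    i <- 0L
    relax <- 0.002  # per-frame pull of the fixation point toward centre
    sacc_steps <- ifelse(magnitude < 4.5, 1L, 2L)
    while (i < n_frames) {
      if (next_sacc <= n_sacc && i == onset_frames[next_sacc]) {
        dx <- magnitude[next_sacc] * cos(deg2rad(angle[next_sacc]))
        dy <- magnitude[next_sacc] * sin(deg2rad(angle[next_sacc]))
        steps <- sacc_steps[next_sacc]
        # exact linear path: onset frame holds the start position,
        # onset + steps holds the end position
        for (k in 0:steps) {
          if (i + k < n_frames) {
            az[i + k + 1L] <- fix_az + dx * k / steps
            el[i + k + 1L] <- fix_el + dy * k / steps
          }
        }
        fix_az <- fix_az + dx
        fix_el <- fix_el + dy
        i <- i + steps + 1L
        next_sacc <- next_sacc + 1L
      } else {
        fix_az <- fix_az * (1 - relax)
        fix_el <- fix_el * (1 - relax)
        az[i + 1L] <- fix_az + stats::rnorm(1, 0, config$fixation_noise_sd)
        el[i + 1L] <- fix_el + stats::rnorm(1, 0, config$fixation_noise_sd)
        i <- i + 1L
      }
    }

    if (config$dropout_rate > 0) {
      drop <- stats::runif(n_frames) < config$dropout_rate
      az[drop] <- NA_real_
      el[drop] <- NA_real_
    }

    trace <- gaze_trace(az, el, fr)
    saccades <- data.frame(
      onset_frame = onset_frames,
      offset_frame = onset_frames + sacc_steps,
      direction = direction,
      magnitude = magnitude,
      angle_deg = angle,
      stringsAsFactors = FALSE
    )
    list(trace = trace,
         ground_truth = list(saccades = saccades, config = config))
  })
}

#' Construct a gaze-trace object
#'
#' @param azimuth_deg,elevation_deg numeric vectors of equal length
#'   (degrees); `NA` marks missing frames.
#' @param frame_rate frames per second.
#' @return A data frame of class `gaze_trace` with columns `frame`
#'   (0-based), `azimuth_deg`, `elevation_deg` and attribute `frame_rate`.
#' @export
gaze_trace <- function(azimuth_deg, elevation_deg, frame_rate) {
  if (length(azimuth_deg) != length(elevation_deg)) {
    stop_invalid_input("azimuth and elevation must have equal length")
  }
  if (!is_pos_scalar(frame_rate)) stop_invalid_input("frame_rate must be > 0")
  out <- data.frame(frame = seq_along(azimuth_deg) - 1L,
                    azimuth_deg = as.numeric(azimuth_deg),
                    elevation_deg = as.numeric(elevation_deg))
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("gaze_trace", "data.frame")
  out
}

#' Frame rate of a gaze trace or dF/F matrix
#' @param x object carrying a `frame_rate` attribute.
#' @return frames per second.
#' @export
frame_rate <- function(x) {
  fr <- attr(x, "frame_rate")
  if (is.null(fr)) stop_invalid_input("object has no frame_rate attribute")
  fr
}

#' Generate a synthetic dF/F matrix from ground-truth saccades
#'
#' Each neuron's trace is `baseline + noise + sum over relevant saccades of
#' amplitude x causal exponential kernel` (decay `kernel_tau`) starting at
#' the saccade onset. The sign is negative for suppressed neurons;
#' `ds_nasal` / `ds_temporal` neurons respond only to saccades of the
#' matching direction; `null` neurons receive no event term.
#'
#' @param ground_truth ground-truth list from [generate_gaze_trace()] (or a
#'   list with a `saccades` data frame holding `onset_frame` and
#'   `direction`).
#' @param specs list of [neuron_spec()] objects, one per neuron.
#' @param n_frames number of imaging frames.
#' @param frame_rate imaging frame rate in Hz.
#' @param rng_seed integer seed for the noise.
#' @param saccade_gain optional numeric vector, one multiplicative gain per
#'   ground-truth saccade (e.g. to attenuate responses during a particular
#'   stimulus); default all 1.
#' @return A numeric matrix (neurons x frames) of class `dff_matrix` with a
#'   `frame_rate` attribute and a `true_class` attribute recording the
#'   per-neuron labels.
#' @export
generate_dff <- function(ground_truth, specs, n_frames, frame_rate,
                         rng_seed = NULL, saccade_gain = NULL) {
  if (length(specs) == 0) stop_invalid_input("specs must list at least one neuron")
  if (inherits(specs, "neuron_spec")) specs <- list(specs)
  if (!all(vapply(specs, inherits, logical(1), "neuron_spec"))) {
    stop_invalid_input("specs must be neuron_spec objects")
  }
  sacc <- ground_truth$saccades
  if (!is.null(sacc) && nrow(sacc) > 0 && any(sacc$onset_frame >= n_frames)) {
    stop_invalid_input("ground-truth saccade frames must be < n_frames")
  }
  if (is.null(saccade_gain)) {
    saccade_gain <- rep(1, if (is.null(sacc)) 0 else nrow(sacc))
  } else if (length(saccade_gain) != nrow(sacc)) {
    stop_invalid_input("saccade_gain must have one entry per saccade")
  }
  local_seed(rng_seed, {
    n_neurons <- length(specs)
    out <- matrix(0, n_neurons, n_frames)
    t_rel <- 0:(n_frames - 1L)
    for (j in seq_len(n_neurons)) {
      sp <- specs[[j]]
      trace <- sp$baseline + stats::rnorm(n_frames, 0, sp$noise_sd)
      if (sp$true_class != "null" && !is.null(sacc) && nrow(sacc) > 0) {
        sign <- if (sp$true_class == "suppressed") -1 else 1
        relevant <- switch(sp$true_class,
          ds_nasal = sacc$direction == "nasal",
          ds_temporal = sacc$direction == "temporal",
          rep(TRUE, nrow(sacc))
        )
        for (i in which(relevant)) {
          o <- sacc$onset_frame[i]
          idx <- (o + 1L):n_frames
          trace[idx] <- trace[idx] + sign * sp$amplitude * saccade_gain[i] *
            exp(-(t_rel[seq_along(idx)]) / (sp$kernel_tau * frame_rate))
        }
      }
      out[j, ] <- trace
    }
    attr(out, "frame_rate") <- frame_rate
    attr(out, "true_class") <- vapply(specs, `[[`, character(1), "true_class")
    class(out) <- c("dff_matrix", class(out))
    out
  })
}

#' Generate a stimulus-epoch table
#'
#' Lays out contiguous, non-overlapping stimulus epochs covering
#' `[0, n_frames)`. The template gives stimulus labels and target durations
#' in frames; any remaining frames are absorbed by the final epoch.
#'
#' @param template data frame with columns `stimulus` (label, e.g. from
#'   DG, SG, LSN-4, LSN-8, NS, NM-1, NM-2, NM-3, S) and `duration`
#'   (frames). A stimulus may appear several times (interleaved blocks).
#' @param n_frames total session length in frames.
#' @return Data frame with `stimulus`, `start_frame` (inclusive, 0-based)
#'   and `end_frame` (exclusive) partitioning the frame axis.
#' @export
generate_stimulus_epochs <- function(template, n_frames) {
  if (!is.data.frame(template) ||
      !all(c("stimulus", "duration") %in% names(template)) ||
      nrow(template) == 0) {
    stop_invalid_input("template must have columns stimulus, duration")
  }
  dur <- as.integer(round(template$duration))
  if (any(dur <= 0)) stop_invalid_input("epoch durations must be positive")
  if (sum(dur) > n_frames) {
    stop_invalid_input("template durations exceed n_frames")
  }
  start <- cumsum(c(0L, dur[-length(dur)]))
  end <- cumsum(dur)
  end[length(end)] <- n_frames  # last epoch absorbs the remainder
  data.frame(stimulus = as.character(template$stimulus),
             start_frame = start, end_frame = end,
             stringsAsFactors = FALSE)
}

#' Default eight-stimulus session template
#'
#' An equal split of the session across the eight stimulus classes used in
#' visual-coding sessions (drifting/static gratings, locally sparse noise
#' at two scales, natural scenes, three natural movies, and the spontaneous
#' mean-luminance gray screen).
#'
#' @param n_frames total frames to divide.
#' @param stimuli character vector of labels.
#' @return A template data frame for [generate_stimulus_epochs()].
#' @export
default_session_template <- function(n_frames,
                                     stimuli = c("DG", "SG", "LSN-4", "LSN-8",
                                                 "NS", "NM-1", "NM-2", "NM-3",
                                                 "S")) {
  data.frame(stimulus = stimuli,
             duration = rep(floor(n_frames / length(stimuli)), length(stimuli)),
             stringsAsFactors = FALSE)
}
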