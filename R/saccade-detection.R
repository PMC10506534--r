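# Saccade detection from angular eye-position traces.
#
# The detector follows a two-threshold speed rule: frames whose speed
# exceeds max(mu + 3 sigma, 10 deg/s) seed candidate events, which are
# extended to the maximal contiguous run of frames whose speed exceeds
# mu + 1 sigma. Candidates are then validated against the positional noise
# in 300 ms windows flanking the event, and classified by direction.

#' Per-frame eye-speed profile
#'
#' Speed at interval `t` (between 0-based frames `t` and `t + 1`) is the
#' Euclidean step length in (azimuth, elevation) degree space times the
#' frame rate, i.e. degrees per second. Intervals touching a missing frame
#' are missing. `mu` and `sigma` are the mean and SD over non-missing
#' speeds; the outlier threshold is `max(mu + n_sigma_outlier * sigma,
#' min_speed_floor)` and the extension threshold is
#' `mu + n_sigma_extend * sigma`.
#'
#' @param trace a [gaze_trace()].
#' @param min_speed_floor lower bound on the outlier threshold, deg/s
#'   (default 10).
#' @param n_sigma_outlier,n_sigma_extend multiples of sigma for the two
#'   thresholds (defaults 3 and 1).
#' @return An object of class `speed_profile`: list with `speed` (length
#'   `n - 1`), `mu`, `sigma`, `outlier_threshold`, `extension_threshold`,
#'   `frame_rate`, `n_frames`.
#' @export
compute_speed <- function(trace, min_speed_floor = 10,
                          n_sigma_outlier = 3, n_sigma_extend = 1) {
  if (nrow(trace) < 2) stop_invalid_input("trace needs at least 2 frames")
  fr <- frame_rate(trace)
  daz <- diff(trace$azimuth_deg)
  del <- diff(trace$elevation_deg)
  speed <- sqrt(daz^2 + del^2) * fr
  ok <- !is.na(speed)
  if (!any(ok)) stop_invalid_input("all frames missing: empty speed profile")
  mu <- mean(speed[ok])
  sigma <- stats::sd(speed[ok])
  if (is.na(sigma)) sigma <- 0
  structure(list(
    speed = speed, mu = mu, sigma = sigma,
    outlier_threshold = max(mu + n_sigma_outlier * sigma, min_speed_floor),
    extension_threshold = mu + n_sigma_extend * sigma,
    frame_rate = fr, n_frames = nrow(trace)
  ), class = "speed_profile")
}

#' Candidate saccade intervals from a speed profile
#'
#' Finds every interval whose speed exceeds the outlier threshold and
#' extends it to the maximal contiguous run of intervals above the
#' extension threshold; runs sharing frames are merged. Returned intervals
#' are in 0-based position-frame coordinates: `onset_frame` is the first
#' frame of the movement, `offset_frame` the last (one past the final
#' above-threshold speed interval).
#'
#' @param profile a [compute_speed()] result.
#' @return Data frame with `onset_frame`, `offset_frame` (possibly empty).
#' @export
detect_candidates <- function(profile) {
  sp <- profile$speed
  above_ext <- !is.na(sp) & sp > profile$extension_threshold
  above_out <- !is.na(sp) & sp > profile$outlier_threshold
  empty <- data.frame(onset_frame = integer(0), offset_frame = integer(0))
  if (!any(above_out)) return(empty)
  r <- rle(above_ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  onsets <- integer(0)
  offsets <- integer(0)
  for (k in which(keep)) {
    if (any(above_out[starts[k]:ends[k]])) {
      onsets <- c(onsets, starts[k] - 1L)   # 0-based interval index
      offsets <- c(offsets, ends[k])        # interval index + 1 = last frame
    }
  }
  if (length(onsets) == 0) return(empty)
  data.frame(onset_frame = onsets, offset_frame = offsets)
}

#' Validate one candidate saccade against flanking noise
#'
#' Computes the positional SD in the 300 ms before onset and the 300 ms
#' after offset, separately per dimension. A candidate with any missing
#' frame in either window (or with windows extending outside the trace) is
#' invalid. Otherwise it is valid iff its absolute position change from
#' onset to offset exceeds `noise_mult * max(sd_before, sd_after)` in at
#' least one dimension. With zero noise on both sides the threshold floor
#' is 0, so any nonzero displacement validates.
#'
#' @param trace a [gaze_trace()].
#' @param onset_frame,offset_frame candidate bounds (0-based frames).
#' @param noise_window_ms flanking window length (default 300 ms).
#' @param noise_mult threshold multiplier (default 3).
#' @return List with `valid` (logical) and `context` (list: per-dimension
#'   `sd_before`, `sd_after`, `threshold`, `delta`, and `any_missing`).
#' @export
validate_saccade <- function(trace, onset_frame, offset_frame,
                             noise_window_ms = 300, noise_mult = 3) {
  fr <- frame_rate(trace)
  w <- as.integer(round(noise_window_ms / 1000 * fr))
  n <- nrow(trace)
  ctx <- list(sd_before = c(NA_real_, NA_real_),
              sd_after = c(NA_real_, NA_real_),
              threshold = c(NA_real_, NA_real_),
              delta = c(NA_real_, NA_real_),
              any_missing = NA)
  pre_idx <- (onset_frame - w):(onset_frame - 1L)
  post_idx <- (offset_frame + 1L):(offset_frame + w)
  if (onset_frame - w < 0L || offset_frame + w > n - 1L) {
    return(list(valid = FALSE, context = ctx))  # insufficient context
  }
  pos <- cbind(trace$azimuth_deg, trace$elevation_deg)
  pre <- pos[pre_idx + 1L, , drop = FALSE]
  post <- pos[post_idx + 1L, , drop = FALSE]
  endpoints <- pos[c(onset_frame, offset_frame) + 1L, , drop = FALSE]
  any_missing <- anyNA(pre) || anyNA(post) || anyNA(endpoints)
  ctx$any_missing <- any_missing
  if (any_missing) return(list(valid = FALSE, context = ctx))
  sd_b <- apply(pre, 2, stats::sd)
  sd_a <- apply(post, 2, stats::sd)
  thr <- noise_mult * pmax(sd_b, sd_a)
  delta <- endpoints[2, ] - endpoints[1, ]
  ctx$sd_before <- sd_b
  ctx$sd_after <- sd_a
  ctx$threshold <- thr
  ctx$delta <- delta
  list(valid = any(abs(delta) > thr), context = ctx)
}

#' Classify a saccade's direction from its displacement
#'
#' The displacement angle `atan2(d_elevation, d_azimuth)` is mapped to
#' `[0, 360)` degrees. Temporal saccades fall within 45 degrees of the
#' +azimuth axis (`[315, 360) U [0, 45)`), nasal saccades within 45 degrees
#' of the -azimuth axis (`[135, 225)`); everything else (dorsal/ventral)
#' is `"other"`. Sector bounds are half-open, so an angle of exactly 45
#' degrees classifies as `"other"`.
#'
#' @param d_azimuth,d_elevation displacement components in degrees.
#' @return `"temporal"`, `"nasal"` or `"other"`.
#' @export
classify_direction <- function(d_azimuth, d_elevation) {
  if (d_azimuth == 0 && d_elevation == 0) {
    stop_invalid_input("zero displacement: direction undefined")
  }
  ang <- rad2deg(atan2(d_elevation, d_azimuth)) %% 360
  if (ang >= 315 || ang < 45) return("temporal")
  if (ang >= 135 && ang < 225) return("nasal")
  "other"
}

#' Detect, validate and classify saccades in a gaze trace
#'
#' Composes [compute_speed()], [detect_candidates()], [validate_saccade()]
#' and [classify_direction()], and attaches the stimulus label of the
#' epoch containing each onset frame.
#'
#' @param trace a [gaze_trace()].
#' @param epochs optional epoch table (`stimulus`, `start_frame`,
#'   `end_frame` with `end_frame` exclusive); events outside all epochs, or
#'   with `epochs = NULL`, are labeled `"unlabeled"`.
#' @param min_speed_floor,n_sigma_outlier,n_sigma_extend see
#'   [compute_speed()].
#' @param noise_window_ms,noise_mult see [validate_saccade()].
#' @param keep_invalid if `TRUE`, rejected candidates are kept with
#'   `valid = FALSE`; default drops them.
#' @return Data frame of saccade events: `onset_frame`, `offset_frame`,
#'   `start_azimuth`, `start_elevation`, `end_azimuth`, `end_elevation`,
#'   `d_azimuth`, `d_elevation`, `magnitude`, `angle_deg`, `direction`,
#'   `valid`, `stimulus`. Ordered and non-overlapping.
#' @export
detect_saccades <- function(trace, epochs = NULL,
                            min_speed_floor = 10, n_sigma_outlier = 3,
                            n_sigma_extend = 1, noise_window_ms = 300,
                            noise_mult = 3, keep_invalid = FALSE) {
  empty <- data.frame(
    onset_frame = integer(0), offset_frame = integer(0),
    start_azimuth = numeric(0), start_elevation = numeric(0),
    end_azimuth = numeric(0), end_elevation = numeric(0),
    d_azimuth = numeric(0), d_elevation = numeric(0),
    magnitude = numeric(0), angle_deg = numeric(0),
    direction = character(0), valid = logical(0), stimulus = character(0),
    stringsAsFactors = FALSE
  )
  if (all(is.na(trace$azimuth_deg))) return(empty)
  if (!is.null(epochs) && nrow(epochs) > 0 &&
      max(epochs$end_frame) > nrow(trace)) {
    stop_invalid_input("epochs extend past the end of the trace: frame axes mismatch")
  }
  profile <- compute_speed(trace, min_speed_floor, n_sigma_outlier, n_sigma_extend)
  cand <- detect_candidates(profile)
  if (nrow(cand) == 0) return(empty)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    on <- cand$onset_frame[i]
    off <- cand$offset_frame[i]
    v <- validate_saccade(trace, on, off, noise_window_ms, noise_mult)
    p0 <- c(trace$azimuth_deg[on + 1L], trace$elevation_deg[on + 1L])
    p1 <- c(trace$azimuth_deg[off + 1L], trace$elevation_deg[off + 1L])
    d <- p1 - p0
    if (anyNA(d) || all(d == 0)) {
      dir <- NA_character_; ang <- NA_real_; mag <- NA_real_
    } else {
      dir <- classify_direction(d[1], d[2])
      ang <- rad2deg(atan2(d[2], d[1])) %% 360
      mag <- sqrt(sum(d^2))
    }
    data.frame(onset_frame = on, offset_frame = off,
               start_azimuth = p0[1], start_elevation = p0[2],
               end_azimuth = p1[1], end_elevation = p1[2],
               d_azimuth = d[1], d_elevation = d[2],
               magnitude = mag, angle_deg = ang,
               direction = dir, valid = v$valid,
               stimulus = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stimulus <- epoch_label(out$onset_frame, epochs)
  if (!keep_invalid) out <- out[out$valid, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Stimulus label of the epoch containing each 0-based frame.
epoch_label <- function(frames, epochs) {
  if (is.null(epochs) || nrow(epochs) == 0) {
    return(rep("unlabeled", length(frames)))
  }
  vapply(frames, function(f) {
    hit <- which(epochs$start_frame <= f & f < epochs$end_frame)
    if (length(hit) == 0) "unlabeled" else epochs$stimulus[hit[1]]
  }, character(1))
}

#' Keep only saccades preceded by steady gaze
#'
#' Retains events whose onset follows the previous event's offset by at
#' least `min_quiet_s` seconds of saccade-free trace. The first event is
#' retained only if at least `min_quiet_s` of trace precedes its onset.
#' The quiet requirement is evaluated against the full input event list,
#' so a retained event may follow a dropped one.
#'
#' @param events saccade event data frame (ordered by onset).
#' @param frame_rate frames per second.
#' @param min_quiet_s minimum saccade-free time before onset (default 2 s).
#' @return The filtered event data frame.
#' @export
steady_gaze_filter <- function(events, frame_rate, min_quiet_s = 2) {
  if (nrow(events) == 0) return(events)
  onset_s <- events$onset_frame / frame_rate
  offset_s <- events$offset_frame / frame_rate
  quiet <- onset_s - c(-Inf, offset_s[-length(offset_s)])
  quiet[1] <- onset_s[1]  # time since session start
  events[quiet >= min_quiet_s, , drop = FALSE]
}
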