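# Saccade-locked neural response analysis: event-triggered dF/F changes,
# Wilcoxon modulation screens with BH-FDR, a session-weighted bootstrap
# null for saccade-responsive (SR) classification, direction selectivity,
# and stimulus-conditioned response comparisons.

#' Response and baseline windows relative to saccade onset
#'
#' All windows are closed frame intervals relative to the 0-based onset
#' frame: the response window spans frames 0 to 10 (0-333 ms at 30 Hz),
#' the deep baseline frames -45 to -15 (-1.5 to -0.5 s; used for the
#' saccade response and the bootstrap null), and the shallow baseline
#' frames -20 to -10 (used by the paired modulation test).
#'
#' @param response,deep_baseline,shallow_baseline integer length-2 vectors
#'   of inclusive frame offsets.
#' @return An object of class `response_windows`.
#' @export
response_windows <- function(response = c(0L, 10L),
                             deep_baseline = c(-45L, -15L),
                             shallow_baseline = c(-20L, -10L)) {
  chk <- function(w, nm) {
    if (length(w) != 2 || w[1] > w[2]) {
      stop_invalid_config(paste0(nm, " must be an ordered length-2 window"))
    }
    as.integer(w)
  }
  structure(list(response = chk(response, "response"),
                 deep_baseline = chk(deep_baseline, "deep_baseline"),
                 shallow_baseline = chk(shallow_baseline, "shallow_baseline")),
            class = "response_windows")
}

#' Saccade-triggered change in dF/F
#'
#' The response to a saccade is the mean dF/F over the response window
#' minus the mean over the deep baseline window. Saccades whose windows do
#' not fit inside the trace yield `NA` (skip marker).
#'
#' @param trace numeric dF/F vector for one neuron.
#' @param onset 0-based saccade onset frame.
#' @param windows a [response_windows()].
#' @return The change in dF/F, or `NA` if a window is out of bounds.
#' @export
saccade_response <- function(trace, onset, windows = response_windows()) {
  n <- length(trace)
  r <- windows$response
  b <- windows$deep_baseline
  if (onset + b[1] < 0L || onset + r[2] > n - 1L) return(NA_real_)
  post <- mean(trace[(onset + r[1]):(onset + r[2]) + 1L])
  pre <- mean(trace[(onset + b[1]):(onset + b[2]) + 1L])
  post - pre
}

# Responses at every possible onset frame (linear-time, cumulative sums).
# Element o + 1 is the response for 0-based onset o; NA where a window
# falls outside the trace.
saccade_response_profile <- function(trace, windows = response_windows()) {
  r <- windows$response
  b <- windows$deep_baseline
  window_mean_profile(trace, r[1], r[2]) -
    window_mean_profile(trace, b[1], b[2])
}

#' Per-saccade response matrix for a population
#'
#' @param dff neurons x frames dF/F matrix.
#' @param onsets integer vector of 0-based saccade onset frames.
#' @param windows a [response_windows()].
#' @return Matrix (neurons x saccades) of dF/F changes; `NA` columns where
#'   the windows do not fit.
#' @export
per_saccade_responses <- function(dff, onsets, windows = response_windows()) {
  n <- ncol(dff)
  r <- windows$response
  b <- windows$deep_baseline
  out <- matrix(NA_real_, nrow(dff), length(onsets))
  for (k in seq_along(onsets)) {
    o <- onsets[k]
    if (o + b[1] < 0L || o + r[2] > n - 1L) next
    post <- rowMeans(dff[, (o + r[1]):(o + r[2]) + 1L, drop = FALSE])
    pre <- rowMeans(dff[, (o + b[1]):(o + b[2]) + 1L, drop = FALSE])
    out[, k] <- post - pre
  }
  out
}

#' Wilcoxon modulation tests for one neuron
#'
#' Two screens for saccade-modulated activity: (1) a paired Wilcoxon
#' signed-rank test of the post-saccade window mean (frames 0-10) against
#' the shallow pre-saccade baseline mean (frames -20 to -10), one pair per
#' saccade; (2) a Wilcoxon rank-sum test of the post-saccade window means
#' for nasal versus temporal saccades. Population-level flagging is done
#' afterwards with [modulation_flags()].
#'
#' @param trace numeric dF/F vector for one neuron.
#' @param events saccade event data frame (`onset_frame`, `direction`).
#' @param windows a [response_windows()].
#' @return List with `p_signed_rank` and `p_rank_sum` (`NA` when a test is
#'   undefined: all paired differences zero, or an empty direction group).
#' @export
modulation_tests <- function(trace, events, windows = response_windows()) {
  n <- length(trace)
  r <- windows$response
  s <- windows$shallow_baseline
  ok <- events$onset_frame + s[1] >= 0L & events$onset_frame + r[2] <= n - 1L
  ev <- events[ok, , drop = FALSE]
  if (nrow(ev) == 0) return(list(p_signed_rank = NA_real_, p_rank_sum = NA_real_))
  post_prof <- window_mean_profile(trace, r[1], r[2])
  pre_prof <- window_mean_profile(trace, s[1], s[2])
  post <- post_prof[ev$onset_frame + 1L]
  pre <- pre_prof[ev$onset_frame + 1L]
  p1 <- tryCatch({
    if (all(post == pre)) NA_real_
    else suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE)$p.value)
  }, error = function(e) NA_real_)
  pn <- post[ev$direction == "nasal"]
  pt <- post[ev$direction == "temporal"]
  p2 <- if (length(pn) == 0 || length(pt) == 0) NA_real_ else {
    tryCatch(suppressWarnings(stats::wilcox.test(pn, pt)$p.value),
             error = function(e) NA_real_)
  }
  list(p_signed_rank = p1, p_rank_sum = p2)
}

#' Benjamini-Hochberg flagging of modulation tests across a population
#'
#' Adjusts each test's p-values across all neurons with the
#' Benjamini-Hochberg procedure (separately per test) and flags a neuron
#' as modulated if either adjusted p-value is at most `fdr`.
#'
#' @param tests data frame with columns `p_signed_rank` and `p_rank_sum`
#'   (one row per neuron; `NA` allowed).
#' @param fdr false discovery rate (default 0.10).
#' @return The input with added columns `p_signed_rank_adj`,
#'   `p_rank_sum_adj`, `modulated`.
#' @export
modulation_flags <- function(tests, fdr = 0.10) {
  tests$p_signed_rank_adj <- stats::p.adjust(tests$p_signed_rank, method = "BH")
  tests$p_rank_sum_adj <- stats::p.adjust(tests$p_rank_sum, method = "BH")
  a1 <- !is.na(tests$p_signed_rank_adj) & tests$p_signed_rank_adj <= fdr
  a2 <- !is.na(tests$p_rank_sum_adj) & tests$p_rank_sum_adj <= fdr
  tests$modulated <- a1 | a2
  tests
}

#' Session-weighted bootstrap null of saccade responses
#'
#' Builds the null distribution of dF/F changes for one neuron: each of
#' `n_samples` draws picks a session with probability proportional to its
#' saccade count, picks an onset frame uniformly at random among frames
#' whose response and deep-baseline windows fit inside that session (and,
#' optionally, within a whitelist such as the spontaneous epochs), and
#' computes the saccade response at that frame.
#'
#' @param traces list of numeric dF/F vectors, one per session in which
#'   the neuron was recorded.
#' @param saccade_counts numeric vector of per-session saccade totals
#'   (session weights).
#' @param windows a [response_windows()].
#' @param n_samples number of bootstrap samples (default 40,000).
#' @param seed integer seed.
#' @param frame_whitelist optional list (parallel to `traces`) of 0-based
#'   onset frames allowed per session, or `NULL` for all frames.
#' @return An object of class `bootstrap_null`: list with `samples`,
#'   `n_samples`, `weights`, `seed`.
#' @export
build_bootstrap_null <- function(traces, saccade_counts,
                                 windows = response_windows(),
                                 n_samples = 40000, seed = NULL,
                                 frame_whitelist = NULL) {
  if (!is.list(traces) || length(traces) == 0) {
    stop_invalid_input("traces must be a non-empty list of sessions")
  }
  if (length(saccade_counts) != length(traces)) {
    stop_invalid_input("one saccade count per session is required")
  }
  values <- vector("list", length(traces))
  for (s in seq_along(traces)) {
    prof <- saccade_response_profile(traces[[s]], windows)
    keep <- !is.na(prof)
    if (!is.null(frame_whitelist)) {
      allow <- rep(FALSE, length(prof))
      wl <- frame_whitelist[[s]]
      allow[wl[wl >= 0 & wl < length(prof)] + 1L] <- TRUE
      keep <- keep & allow
    }
    values[[s]] <- prof[keep]
  }
  usable <- vapply(values, length, integer(1)) > 0 & saccade_counts > 0
  if (!any(usable)) {
    abort_sc("no frame admits both windows in any weighted session",
             "saccadescope_null_construction")
  }
  w <- saccade_counts * usable
  w <- w / sum(w)
  samples <- local_seed(seed, {
    sess <- sample.int(length(traces), n_samples, replace = TRUE, prob = w)
    out <- numeric(n_samples)
    for (s in which(usable)) {
      take <- sess == s
      if (any(take)) {
        out[take] <- values[[s]][sample.int(length(values[[s]]),
                                            sum(take), replace = TRUE)]
      }
    }
    out
  })
  structure(list(samples = samples, n_samples = n_samples,
                 weights = w, seed = seed),
            class = "bootstrap_null")
}

#' @export
print.bootstrap_null <- function(x, ...) {
  cat("Bootstrap null:", x$n_samples, "samples across",
      length(x$weights), "session(s)\n")
  invisible(x)
}

#' Classify a neuron against its bootstrap null
#'
#' The quantile of the observed mean saccade response within the null is
#' computed with mid-rank tie handling,
#' `q = (#\{null < obs\} + 0.5 #\{null = obs\}) / n`. The neuron is
#' `enhanced` if `q >= 1 - p`, `suppressed` if `q <= p`, otherwise `none`.
#'
#' @param mean_response observed mean saccade response (dF/F change).
#' @param null a [build_bootstrap_null()] object (or numeric vector of
#'   null samples).
#' @param p tail probability threshold (default 5e-4; from roughly 32,000
#'   neurons this admits ~16 expected false positives).
#' @return List with `mean_response`, `q`, `class`, `p_threshold`.
#' @export
classify_sr <- function(mean_response, null, p = 5e-4) {
  samples <- if (inherits(null, "bootstrap_null")) null$samples else null
  if (length(samples) == 0) stop_invalid_input("empty null distribution")
  if (is.na(mean_response)) {
    return(list(mean_response = NA_real_, q = NA_real_, class = NA_character_,
                p_threshold = p))
  }
  n <- length(samples)
  q <- (sum(samples < mean_response) + 0.5 * sum(samples == mean_response)) / n
  cls <- if (q >= 1 - p) "enhanced" else if (q <= p) "suppressed" else "none"
  list(mean_response = mean_response, q = q, class = cls, p_threshold = p)
}

#' Expected false positives of the two-tailed bootstrap threshold
#'
#' With tail probability `p` per tail, a population of `n_neurons` null
#' neurons yields about `n_neurons * p` false positives per tail.
#'
#' @param n_neurons population size.
#' @param p tail probability (default 5e-4).
#' @param tails count one tail (default, matching the usual back-of-
#'   envelope justification) or both.
#' @return Expected number of false positives.
#' @export
expected_false_positives <- function(n_neurons, p = 5e-4, tails = 1) {
  n_neurons * p * tails
}

#' Direction selectivity of a saccade-responsive neuron
#'
#' An SR neuron is direction selective (DS) if (1) it has an enhanced
#' response to saccades and (2) its responses to nasal and temporal
#' saccades differ significantly (Wilcoxon rank-sum, `p < alpha`). The
#' rank-sum test compares the post-onset window means per direction; the
#' preferred direction and the saccade DSI `(T - N) / (T + N)` use the
#' mean saccade responses (dF/F changes) `T` and `N` per direction. Since
#' `T` and `N` can be negative, the DSI is not confined to `[-1, 1]`.
#'
#' @param resp_temporal,resp_nasal per-saccade dF/F changes by direction.
#' @param sr_class classification from [classify_sr()] (`"enhanced"`,
#'   `"suppressed"` or `"none"`).
#' @param post_temporal,post_nasal optional post-onset window means per
#'   direction for the rank-sum test; the dF/F changes are used when
#'   omitted.
#' @param alpha significance level for the rank-sum test (default 0.05).
#' @return List with `ds`, `preferred_direction` (`"temporal"`, `"nasal"`
#'   or `"none"`), `T`, `N`, `saccade_dsi`, `p_rank_sum`.
#' @export
classify_ds <- function(resp_temporal, resp_nasal, sr_class,
                        post_temporal = NULL, post_nasal = NULL,
                        alpha = 0.05) {
  if (is.null(post_temporal)) post_temporal <- resp_temporal
  if (is.null(post_nasal)) post_nasal <- resp_nasal
  Tm <- if (length(resp_temporal)) mean(resp_temporal, na.rm = TRUE) else NA_real_
  Nm <- if (length(resp_nasal)) mean(resp_nasal, na.rm = TRUE) else NA_real_
  dsi <- if (is.na(Tm) || is.na(Nm) || (Tm + Nm) == 0) NA_real_ else {
    (Tm - Nm) / (Tm + Nm)
  }
  p_rs <- if (length(post_temporal) == 0 || length(post_nasal) == 0) NA_real_ else {
    tryCatch(suppressWarnings(stats::wilcox.test(post_temporal, post_nasal)$p.value),
             error = function(e) NA_real_)
  }
  ds <- identical(sr_class, "enhanced") && !is.na(p_rs) && p_rs < alpha
  pref <- if (!ds || is.na(Tm) || is.na(Nm)) "none" else {
    if (Tm > Nm) "temporal" else "nasal"
  }
  list(ds = ds, preferred_direction = pref, T = Tm, N = Nm,
       saccade_dsi = dsi, p_rank_sum = p_rs)
}

#' Container-level saccade-count inclusion rule
#'
#' Experiment containers with fewer than `min_nasal` nasal or fewer than
#' `min_temporal` temporal saccades (counted after steady-gaze filtering)
#' are excluded from the neural analysis.
#'
#' @param events saccade event data frame with a `direction` column
#'   (pooled over the container's sessions).
#' @param min_nasal,min_temporal minimum counts (defaults 15 and 15; the
#'   spontaneous-only variant uses 3 and 3).
#' @return `TRUE` to keep the container.
#' @export
container_inclusion <- function(events, min_nasal = 15, min_temporal = 15) {
  n_nasal <- sum(events$direction == "nasal", na.rm = TRUE)
  n_temporal <- sum(events$direction == "temporal", na.rm = TRUE)
  n_nasal >= min_nasal && n_temporal >= min_temporal
}

#' Classify all neurons of an experiment container
#'
#' Runs the full SR pipeline for a container of 1-3 sessions with matched
#' neurons: steady-gaze filtering, container inclusion, pooled per-saccade
#' responses, the session-weighted bootstrap null, tail-quantile SR
#' classification, direction selectivity, and the per-neuron Wilcoxon
#' modulation screens (BH-flagged across the container's neurons).
#'
#' The spontaneous-only variant (`spontaneous_only = TRUE`) restricts both
#' the saccades and the bootstrap null frames to the spontaneous
#' (gray-screen) epochs and uses the relaxed 3/3 direction minima.
#'
#' @param container list of sessions; each session is a list with `dff`
#'   (neurons x frames matrix, same neuron order across sessions, with a
#'   `frame_rate` attribute), `events` (valid saccade events with
#'   `onset_frame`, `direction`, `stimulus`), and `epochs` (epoch table).
#' @param windows a [response_windows()].
#' @param n_boot bootstrap samples per neuron (default 40,000).
#' @param p tail probability for SR classification (default 5e-4).
#' @param alpha_ds rank-sum significance level for DS (default 0.05).
#' @param fdr BH false discovery rate for the modulation screens
#'   (default 0.10).
#' @param seed integer seed; per-neuron seeds are derived from it.
#' @param steady_gaze_s minimum preceding quiet time in seconds
#'   (default 2).
#' @param min_nasal,min_temporal container inclusion minima; defaults 15
#'   and 15 (3 and 3 when `spontaneous_only`).
#' @param spontaneous_only restrict to spontaneous-epoch saccades and
#'   null frames.
#' @param spont_label stimulus label of the spontaneous epochs
#'   (default `"S"`).
#' @return Data frame, one row per neuron: `neuron`, `n_saccades`,
#'   `mean_response`, `q`, `class`, `ds`, `preferred_direction`,
#'   `resp_temporal`, `resp_nasal`, `saccade_dsi`, `p_ds`,
#'   `p_signed_rank`, `p_rank_sum`, adjusted p-values and `modulated`.
#'   Attribute `included` records whether the container passed the
#'   saccade-count rule (when `FALSE` all classification columns are
#'   `NA`).
#' @export
classify_neurons <- function(container, windows = response_windows(),
                             n_boot = 40000, p = 5e-4, alpha_ds = 0.05,
                             fdr = 0.10, seed = NULL, steady_gaze_s = 2,
                             min_nasal = if (spontaneous_only) 3 else 15,
                             min_temporal = if (spontaneous_only) 3 else 15,
                             spontaneous_only = FALSE, spont_label = "S") {
  if (!is.list(container) || length(container) == 0) {
    stop_invalid_input("container must list at least one session")
  }
  n_neurons <- nrow(container[[1]]$dff)
  fr <- frame_rate(container[[1]]$dff)
  for (s in container) {
    if (nrow(s$dff) != n_neurons) {
      stop_invalid_input("all sessions must share the same matched neurons")
    }
  }

  ses_events <- lapply(container, function(s) {
    ev <- steady_gaze_filter(s$events, fr, steady_gaze_s)
    if (spontaneous_only) ev <- ev[ev$stimulus == spont_label, , drop = FALSE]
    ev
  })
  pooled <- do.call(rbind, ses_events)
  included <- container_inclusion(pooled, min_nasal, min_temporal)

  out <- data.frame(
    neuron = seq_len(n_neurons),
    n_saccades = NA_integer_, mean_response = NA_real_, q = NA_real_,
    class = NA_character_, ds = NA, preferred_direction = NA_character_,
    resp_temporal = NA_real_, resp_nasal = NA_real_, saccade_dsi = NA_real_,
    p_ds = NA_real_, p_signed_rank = NA_real_, p_rank_sum = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!included || nrow(pooled) == 0) {
    out <- modulation_flags(out, fdr)
    out$modulated <- NA
    attr(out, "included") <- included
    return(out)
  }

  # per-session response matrices and post-window means
  resp_list <- lapply(seq_along(container), function(si) {
    per_saccade_responses(container[[si]]$dff, ses_events[[si]]$onset_frame,
                          windows)
  })
  r <- windows$response
  post_list <- lapply(seq_along(container), function(si) {
    dff <- container[[si]]$dff
    onsets <- ses_events[[si]]$onset_frame
    m <- matrix(NA_real_, nrow(dff), length(onsets))
    ok <- onsets + r[2] <= ncol(dff) - 1L & onsets + r[1] >= 0L
    for (k in which(ok)) {
      m[, k] <- rowMeans(dff[, (onsets[k] + r[1]):(onsets[k] + r[2]) + 1L,
                             drop = FALSE])
    }
    m
  })
  responses <- do.call(cbind, resp_list)
  post_means <- do.call(cbind, post_list)
  direction <- pooled$direction

  sacc_counts <- vapply(ses_events, nrow, integer(1))
  whitelist <- if (spontaneous_only) {
    lapply(container, function(s) {
      ep <- s$epochs[s$epochs$stimulus == spont_label, , drop = FALSE]
      if (nrow(ep) == 0) integer(0) else {
        unlist(lapply(seq_len(nrow(ep)), function(i) {
          ep$start_frame[i]:(ep$end_frame[i] - 1L)
        }))
      }
    })
  } else NULL

  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  for (j in seq_len(n_neurons)) {
    resp_j <- responses[j, ]
    ok_j <- !is.na(resp_j)
    out$n_saccades[j] <- sum(ok_j)
    if (!any(ok_j)) next
    mean_resp <- mean(resp_j[ok_j])
    traces <- lapply(container, function(s) s$dff[j, ])
    null_j <- build_bootstrap_null(
      traces, sacc_counts, windows, n_samples = n_boot,
      seed = if (is.null(base_seed)) NULL else (base_seed + j) %% .Machine$integer.max,
      frame_whitelist = whitelist
    )
    sr <- classify_sr(mean_resp, null_j, p)
    is_t <- ok_j & direction == "temporal"
    is_n <- ok_j & direction == "nasal"
    ds <- classify_ds(resp_j[is_t], resp_j[is_n], sr$class,
                      post_temporal = post_means[j, is_t],
                      post_nasal = post_means[j, is_n],
                      alpha = alpha_ds)
    out$mean_response[j] <- sr$mean_response
    out$q[j] <- sr$q
    out$class[j] <- sr$class
    out$ds[j] <- ds$ds
    out$preferred_direction[j] <- ds$preferred_direction
    out$resp_temporal[j] <- ds$T
    out$resp_nasal[j] <- ds$N
    out$saccade_dsi[j] <- ds$saccade_dsi
    out$p_ds[j] <- ds$p_rank_sum

    mt <- modulation_tests_pooled(container, ses_events, j, windows)
    out$p_signed_rank[j] <- mt$p_signed_rank
    out$p_rank_sum[j] <- mt$p_rank_sum
  }
  out <- modulation_flags(out, fdr)
  attr(out, "included") <- included
  out
}

# Modulation tests with saccades pooled across a container's sessions.
modulation_tests_pooled <- function(container, ses_events, neuron, windows) {
  post <- numeric(0)
  pre <- numeric(0)
  dirs <- character(0)
  r <- windows$response
  s <- windows$shallow_baseline
  for (si in seq_along(container)) {
    trace <- container[[si]]$dff[neuron, ]
    ev <- ses_events[[si]]
    if (nrow(ev) == 0) next
    ok <- ev$onset_frame + s[1] >= 0L & ev$onset_frame + r[2] <= length(trace) - 1L
    if (!any(ok)) next
    post_prof <- window_mean_profile(trace, r[1], r[2])
    pre_prof <- window_mean_profile(trace, s[1], s[2])
    post <- c(post, post_prof[ev$onset_frame[ok] + 1L])
    pre <- c(pre, pre_prof[ev$onset_frame[ok] + 1L])
    dirs <- c(dirs, ev$direction[ok])
  }
  if (length(post) == 0) return(list(p_signed_rank = NA_real_, p_rank_sum = NA_real_))
  p1 <- tryCatch({
    if (all(post == pre)) NA_real_
    else suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE)$p.value)
  }, error = function(e) NA_real_)
  pn <- post[dirs == "nasal"]
  pt <- post[dirs == "temporal"]
  p2 <- if (length(pn) == 0 || length(pt) == 0) NA_real_ else {
    tryCatch(suppressWarnings(stats::wilcox.test(pn, pt)$p.value),
             error = function(e) NA_real_)
  }
  list(p_signed_rank = p1, p_rank_sum = p2)
}

#' Stimulus-conditioned saccade responses
#'
#' Compares each neuron's mean saccade response during each visual
#' stimulus with its mean response to saccades made during the spontaneous
#' (gray-screen) stimulus. Sessions with fewer than `min_spont` saccades
#' during the spontaneous stimulus are excluded. For direction-selective
#' neurons only saccades in the preferred direction are used; for other
#' neurons all saccades count. Across neurons, each stimulus is compared
#' with the spontaneous stimulus by a paired Wilcoxon signed-rank test.
#'
#' @param container list of sessions (see [classify_neurons()]).
#' @param classifications classification data frame from
#'   [classify_neurons()] (uses `class`, `ds`, `preferred_direction`).
#' @param windows a [response_windows()].
#' @param min_spont minimum spontaneous-stimulus saccades per session
#'   (default 8).
#' @param steady_gaze_s steady-gaze filter length in seconds (default 2).
#' @param spont_label spontaneous stimulus label (default `"S"`).
#' @param neurons optional subset of neuron indices (default: all SR
#'   neurons, i.e. class `enhanced` or `suppressed`).
#' @return List with `per_neuron` (data frame: `neuron`, `stimulus`,
#'   `mean_response`, `ratio`; ratio is `NA` when the spontaneous mean is
#'   not positive) and `tests` (data frame: `stimulus`, `p`, `n_pairs`,
#'   `median_ratio`).
#' @export
stimulus_conditioned_responses <- function(container, classifications,
                                           windows = response_windows(),
                                           min_spont = 8, steady_gaze_s = 2,
                                           spont_label = "S",
                                           neurons = NULL) {
  fr <- frame_rate(container[[1]]$dff)
  ses_events <- lapply(container, function(s) {
    steady_gaze_filter(s$events, fr, steady_gaze_s)
  })
  keep_session <- vapply(ses_events, function(ev) {
    sum(ev$stimulus == spont_label) >= min_spont
  }, logical(1))
  if (!any(keep_session)) {
    abort_sc("no session meets the spontaneous saccade minimum",
             "saccadescope_invalid_input")
  }
  container <- container[keep_session]
  ses_events <- ses_events[keep_session]

  if (is.null(neurons)) {
    neurons <- which(classifications$class %in% c("enhanced", "suppressed"))
  }
  resp_list <- lapply(seq_along(container), function(si) {
    per_saccade_responses(container[[si]]$dff, ses_events[[si]]$onset_frame,
                          windows)
  })
  responses <- do.call(cbind, resp_list)
  pooled <- do.call(rbind, ses_events)
  stimuli <- sort(unique(pooled$stimulus))

  rows <- list()
  for (j in neurons) {
    use <- !is.na(responses[j, ])
    if (isTRUE(classifications$ds[j]) &&
        classifications$preferred_direction[j] %in% c("nasal", "temporal")) {
      use <- use & pooled$direction == classifications$preferred_direction[j]
    }
    means <- vapply(stimuli, function(st) {
      sel <- use & pooled$stimulus == st
      if (!any(sel)) NA_real_ else mean(responses[j, sel])
    }, numeric(1))
    spont_mean <- means[match(spont_label, stimuli)]
    ratio <- if (is.na(spont_mean) || spont_mean <= 0) {
      rep(NA_real_, length(means))
    } else means / spont_mean
    rows[[length(rows) + 1L]] <- data.frame(
      neuron = j, stimulus = stimuli, mean_response = unname(means),
      ratio = unname(ratio), stringsAsFactors = FALSE)
  }
  per_neuron <- do.call(rbind, rows)

  other <- setdiff(stimuli, spont_label)
  tests <- do.call(rbind, lapply(other, function(st) {
    x <- per_neuron$mean_response[per_neuron$stimulus == st]
    y <- per_neuron$mean_response[per_neuron$stimulus == spont_label]
    ok <- !is.na(x) & !is.na(y)
    pv <- if (sum(ok) < 2 || all(x[ok] == y[ok])) NA_real_ else {
      tryCatch(suppressWarnings(
        stats::wilcox.test(x[ok], y[ok], paired = TRUE)$p.value),
        error = function(e) NA_real_)
    }
    rat <- per_neuron$ratio[per_neuron$stimulus == st]
    data.frame(stimulus = st, p = pv, n_pairs = sum(ok),
               median_ratio = stats::median(rat, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(per_neuron = per_neuron, tests = tests)
}
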