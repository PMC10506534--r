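# Behavioral summaries of detected saccades: intersaccade intervals,
# direction/magnitude asymmetry, and per-stimulus saccade frequency with
# distribution comparisons.

#' Intersaccade intervals
#'
#' Intervals are measured onset-to-onset in seconds.
#'
#' @param events saccade event data frame ordered by onset.
#' @param frame_rate frames per second.
#' @param threshold_s interval threshold for the burst fraction
#'   (default 2 s).
#' @return List with `intervals` (seconds; empty if fewer than two events)
#'   and `fraction_leq` (share of intervals at most `threshold_s`;
#'   `NA` if no intervals).
#' @export
intersaccade_intervals <- function(events, frame_rate, threshold_s = 2) {
  if (nrow(events) < 2) {
    return(list(intervals = numeric(0), fraction_leq = NA_real_))
  }
  iv <- diff(events$onset_frame) / frame_rate
  list(intervals = iv, fraction_leq = mean(iv <= threshold_s))
}

#' Per-mouse per-stimulus saccade frequency
#'
#' For each mouse and stimulus, the frequency is the total saccade count
#' divided by the total time that mouse viewed the stimulus, pooled over
#' the mouse's sessions (pooled counts over pooled durations, not a mean
#' of per-session rates). Stimuli a mouse never viewed get `NA`, not 0.
#'
#' @param events saccade event data frame with a `session` column and a
#'   `stimulus` column.
#' @param epochs epoch table with `session`, `stimulus`, `start_frame`,
#'   `end_frame` (exclusive).
#' @param session_mouse data frame mapping `session` to `mouse`.
#' @param frame_rate frames per second.
#' @return Data frame with `mouse`, `stimulus`, `n_saccades`,
#'   `duration_s`, `frequency_hz`.
#' @export
saccade_frequency_by_stimulus <- function(events, epochs, session_mouse,
                                          frame_rate) {
  if (!all(c("session", "stimulus") %in% names(events))) {
    stop_invalid_input("events must carry session and stimulus columns")
  }
  if (!all(c("session", "mouse") %in% names(session_mouse))) {
    stop_invalid_input("session_mouse must have columns session, mouse")
  }
  epochs$mouse <- session_mouse$mouse[match(epochs$session, session_mouse$session)]
  events$mouse <- session_mouse$mouse[match(events$session, session_mouse$session)]
  dur <- stats::aggregate(
    (epochs$end_frame - epochs$start_frame) / frame_rate,
    by = list(mouse = epochs$mouse, stimulus = epochs$stimulus), FUN = sum)
  names(dur)[3] <- "duration_s"
  if (nrow(events) > 0) {
    cnt <- stats::aggregate(rep(1L, nrow(events)),
      by = list(mouse = events$mouse, stimulus = events$stimulus), FUN = sum)
    names(cnt)[3] <- "n_saccades"
  } else {
    cnt <- data.frame(mouse = character(0), stimulus = character(0),
                      n_saccades = integer(0))
  }
  out <- merge(dur, cnt, by = c("mouse", "stimulus"), all.x = TRUE)
  out$n_saccades[is.na(out$n_saccades)] <- 0L
  out$frequency_hz <- ifelse(out$duration_s > 0,
                             out$n_saccades / out$duration_s, NA_real_)
  out[order(out$mouse, out$stimulus), , drop = FALSE]
}

#' Pairwise KS comparison of per-mouse frequency distributions
#'
#' Two-sample Kolmogorov-Smirnov test for every stimulus pair on the
#' per-mouse frequency values, flagged against a Bonferroni-corrected
#' threshold whose divisor is the number of stimuli (0.05 / 8 = 0.00625
#' for the standard eight-stimulus set).
#'
#' @param freq frequency table from [saccade_frequency_by_stimulus()].
#' @param alpha family-wise significance level (default 0.05).
#' @return List with `p` and `statistic` (symmetric matrices; diagonal
#'   p-values are 1), `significant` (logical matrix), `threshold`
#'   (`alpha / n_stimuli`). Pairs where either stimulus has fewer than two
#'   observations are `NA` (untestable).
#' @export
compare_frequency_distributions <- function(freq, alpha = 0.05) {
  stims <- sort(unique(freq$stimulus))
  k <- length(stims)
  if (k < 2) stop_invalid_input("need at least two stimuli to compare")
  p <- stat <- matrix(NA_real_, k, k, dimnames = list(stims, stims))
  diag(p) <- 1
  diag(stat) <- 0
  vals <- lapply(stims, function(s) {
    v <- freq$frequency_hz[freq$stimulus == s]
    v[!is.na(v)]
  })
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (length(vals[[i]]) >= 2 && length(vals[[j]]) >= 2) {
        res <- ks_p(vals[[i]], vals[[j]])
        p[i, j] <- p[j, i] <- res$p.value
        stat[i, j] <- stat[j, i] <- res$statistic
      }
    }
  }
  threshold <- alpha / k
  list(p = p, statistic = stat, significant = !is.na(p) & p < threshold,
       threshold = threshold)
}

#' Nasal/temporal magnitude asymmetry
#'
#' Summarises saccade magnitudes per direction, computes the per-session
#' ratio of mean temporal to mean nasal magnitude, and compares the nasal
#' and temporal magnitude distributions with a two-sample KS test.
#'
#' @param events saccade event data frame with `direction`, `magnitude`
#'   and (optionally) `session` columns; a single session is assumed when
#'   the column is absent.
#' @return List with `by_direction` (data frame: direction, n, mean, sd),
#'   `session_ratio` (data frame: session, ratio; `NA` where a session
#'   lacks either direction), `ks_p` (nasal vs temporal magnitudes;
#'   `NA` if either sample has fewer than two values).
#' @export
magnitude_asymmetry <- function(events) {
  if (!all(c("direction", "magnitude") %in% names(events))) {
    stop_invalid_input("events must carry direction and magnitude")
  }
  if (!"session" %in% names(events)) events$session <- "session1"
  horiz <- events[events$direction %in% c("nasal", "temporal"), , drop = FALSE]
  by_dir <- do.call(rbind, lapply(c("nasal", "temporal"), function(d) {
    m <- horiz$magnitude[horiz$direction == d]
    data.frame(direction = d, n = length(m),
               mean = if (length(m)) mean(m) else NA_real_,
               sd = if (length(m) > 1) stats::sd(m) else NA_real_)
  }))
  sessions <- unique(horiz$session)
  ratio <- vapply(sessions, function(s) {
    tm <- horiz$magnitude[horiz$session == s & horiz$direction == "temporal"]
    nm <- horiz$magnitude[horiz$session == s & horiz$direction == "nasal"]
    if (length(tm) == 0 || length(nm) == 0) NA_real_ else mean(tm) / mean(nm)
  }, numeric(1))
  nasal <- horiz$magnitude[horiz$direction == "nasal"]
  temporal <- horiz$magnitude[horiz$direction == "temporal"]
  ksp <- if (length(nasal) >= 2 && length(temporal) >= 2) {
    ks_p(nasal, temporal)$p.value
  } else NA_real_
  list(by_direction = by_dir,
       session_ratio = data.frame(session = sessions, ratio = unname(ratio),
                                  stringsAsFactors = FALSE),
       ks_p = ksp)
}

#' Bonferroni-corrected threshold for a family of comparisons
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_comparisons family size divisor (e.g. 8 stimuli).
#' @return `alpha / n_comparisons`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_comparisons) {
  if (!is_pos_scalar(n_comparisons)) stop_invalid_input("n_comparisons must be > 0")
  alpha / n_comparisons
}
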