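# Visual response metrics (drifting-grating DSI and OSI, lifetime
# sparseness) and population comparisons between saccade-responsive and
# non-responsive neurons.

#' Preferred drifting-grating condition
#'
#' The preferred condition is the (direction, temporal frequency) pair
#' with the largest trial-mean response. Ties are broken by the lowest
#' temporal frequency, then the smallest direction angle.
#'
#' @param responses numeric matrix of trial-mean responses with directions
#'   (degrees) as rows and temporal frequencies (Hz) as columns; dimnames
#'   must be numeric-coercible.
#' @return List with `direction` and `temporal_frequency` (numeric).
#' @export
preferred_condition <- function(responses) {
  if (!is.matrix(responses) || length(responses) == 0 || all(is.na(responses))) {
    stop_invalid_input("responses must be a non-empty matrix with finite entries")
  }
  dirs <- as.numeric(rownames(responses))
  tfs <- as.numeric(colnames(responses))
  if (anyNA(dirs) || anyNA(tfs)) {
    stop_invalid_input("dimnames must give numeric directions and frequencies")
  }
  best <- max(responses, na.rm = TRUE)
  hits <- which(responses == best, arr.ind = TRUE)
  # tie-break: lowest TF, then smallest direction
  ord <- order(tfs[hits[, 2]], dirs[hits[, 1]])
  pick <- hits[ord[1], ]
  list(direction = dirs[pick[1]], temporal_frequency = tfs[pick[2]])
}

#' Drifting-grating direction selectivity index
#'
#' `DSI = (R_pref - R_null) / (R_pref + R_null)`, where `R_pref` is the
#' mean response at the preferred direction and `R_null` the mean response
#' at the opposite direction at the same temporal frequency.
#'
#' @param r_pref,r_null mean responses.
#' @return The DSI, or `NA` when `r_pref + r_null == 0` (undefined).
#' @export
dg_dsi <- function(r_pref, r_null) {
  if (is.na(r_pref) || is.na(r_null) || (r_pref + r_null) == 0) return(NA_real_)
  (r_pref - r_null) / (r_pref + r_null)
}

#' Orientation selectivity index (circular variance form)
#'
#' `OSI = |sum_theta R_theta exp(2 i theta)| / sum_theta R_theta` with
#' `theta` in radians, the standard orientation-doubling vector average:
#' 1 for response at a single direction (or an opposite-direction pair),
#' 0 for equal responses at equally spaced directions.
#'
#' @param r_theta mean responses per direction.
#' @param theta_deg directions in degrees (same length).
#' @param clip_negative clip negative responses to zero before averaging
#'   (default `TRUE`; the vector average assumes nonnegative weights).
#' @return The OSI in `[0, 1]`, or `NA` if the summed response is not
#'   positive.
#' @export
osi <- function(r_theta, theta_deg, clip_negative = TRUE) {
  if (length(r_theta) != length(theta_deg)) {
    stop_invalid_input("r_theta and theta_deg must have equal length")
  }
  r <- r_theta
  if (clip_negative) r <- pmax(r, 0)
  s <- sum(r)
  if (is.na(s) || s <= 0) return(NA_real_)
  th <- deg2rad(theta_deg)
  Mod(sum(r * exp(2i * th))) / s
}

#' Lifetime sparseness
#'
#' `S_L = (1 - (1/N) (sum r_i)^2 / sum r_i^2) / (1 - 1/N)` over the `N`
#' stimulus conditions: 0 for a uniform response vector, 1 for a one-hot
#' vector.
#'
#' @param r per-condition trial-mean responses (length `N >= 2`).
#' @return The sparseness, or `NA` when `sum r_i^2 == 0`.
#' @export
lifetime_sparseness <- function(r) {
  n <- length(r)
  if (n < 2) stop_invalid_input("lifetime sparseness needs at least 2 conditions")
  ss <- sum(r^2)
  if (is.na(ss) || ss == 0) return(NA_real_)
  (1 - (sum(r)^2 / n) / ss) / (1 - 1 / n)
}

#' Pairwise KS comparison of a metric across groups
#'
#' Two-sample KS test of the metric distribution for every pair of groups,
#' with Bonferroni correction over the number of pairs tested.
#'
#' @param values numeric metric values.
#' @param groups group labels (same length).
#' @param alpha family-wise level (default 0.05).
#' @return List with `p`, `statistic` (symmetric matrices),
#'   `significant`, `threshold` (`alpha` / number of testable pairs).
#'   Pairs involving a group with fewer than two values are `NA`.
#' @export
compare_populations <- function(values, groups, alpha = 0.05) {
  g <- sort(unique(as.character(groups)))
  k <- length(g)
  if (k < 2) stop_invalid_input("need at least two groups")
  p <- stat <- matrix(NA_real_, k, k, dimnames = list(g, g))
  diag(p) <- 1
  diag(stat) <- 0
  vals <- lapply(g, function(gr) {
    v <- values[groups == gr]
    v[!is.na(v)]
  })
  n_pairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (length(vals[[i]]) >= 2 && length(vals[[j]]) >= 2) {
        res <- ks_p(vals[[i]], vals[[j]])
        p[i, j] <- p[j, i] <- res$p.value
        stat[i, j] <- stat[j, i] <- res$statistic
      }
    }
  }
  threshold <- alpha / n_pairs
  list(p = p, statistic = stat,
       significant = !is.na(p) & p < threshold, threshold = threshold)
}

#' Pairwise chi-squared tests of SR rates across categories
#'
#' For each pair of categories, a chi-squared test on the 2 x 2
#' contingency matrix of (SR, non-SR) counts, Bonferroni-corrected over
#' the number of pairs.
#'
#' @param sr_counts named integer vector of SR counts per category.
#' @param totals named integer vector of total neurons per category
#'   (same names).
#' @param alpha family-wise level (default 0.05).
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return List with `p`, `statistic`, `significant`, `threshold`.
#' @export
sr_rate_tests <- function(sr_counts, totals, alpha = 0.05, correct = FALSE) {
  if (length(sr_counts) != length(totals)) {
    stop_invalid_input("sr_counts and totals must align")
  }
  if (any(sr_counts > totals)) stop_invalid_input("sr_counts cannot exceed totals")
  g <- names(sr_counts)
  if (is.null(g)) g <- as.character(seq_along(sr_counts))
  k <- length(g)
  if (k < 2) stop_invalid_input("need at least two categories")
  p <- stat <- matrix(NA_real_, k, k, dimnames = list(g, g))
  diag(p) <- 1
  diag(stat) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      tab <- rbind(c(sr_counts[i], totals[i] - sr_counts[i]),
                   c(sr_counts[j], totals[j] - sr_counts[j]))
      res <- tryCatch(
        suppressWarnings(stats::chisq.test(tab, correct = correct)),
        error = function(e) NULL)
      if (!is.null(res)) {
        p[i, j] <- p[j, i] <- res$p.value
        stat[i, j] <- stat[j, i] <- unname(res$statistic)
      }
    }
  }
  threshold <- alpha / (k * (k - 1) / 2)
  list(p = p, statistic = stat,
       significant = !is.na(p) & p < threshold, threshold = threshold)
}

#' SR-rate breakdown by metadata category
#'
#' Tabulates the fraction of saccade-responsive neurons within each level
#' of one or more metadata columns (transgenic line, visual area, cortical
#' layer, visual response class, ...), with the underlying counts.
#'
#' @param sr logical vector: is each neuron SR?
#' @param metadata data frame of per-neuron labels (same number of rows).
#' @param by character vector of metadata columns to break down by
#'   (default: all columns).
#' @return Data frame with the `by` columns plus `n_sr`, `n_total`,
#'   `rate_pct` (percentage).
#' @export
sr_rate_breakdown <- function(sr, metadata, by = names(metadata)) {
  if (length(sr) != nrow(metadata)) {
    stop_invalid_input("sr flags and metadata must align")
  }
  if (anyNA(metadata[, by, drop = FALSE])) {
    stop_invalid_input("every neuron needs a label in each 'by' column")
  }
  key <- metadata[, by, drop = FALSE]
  tot <- stats::aggregate(rep(1L, length(sr)), by = as.list(key), FUN = sum)
  names(tot)[ncol(tot)] <- "n_total"
  srs <- stats::aggregate(as.integer(sr), by = as.list(key), FUN = sum)
  names(srs)[ncol(srs)] <- "n_sr"
  out <- merge(tot, srs, by = by)
  out$rate_pct <- 100 * out$n_sr / out$n_total
  out[do.call(order, out[by]), c(by, "n_sr", "n_total", "rate_pct"),
      drop = FALSE]
}
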