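# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so that library calls never
#' perturb user-level randomness. With `seed = NULL` the code runs against
#' the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Abort with a classed condition so callers can distinguish config, parse
# and computation errors.
abort_sc <- function(msg, class) {
  stop(structure(
    class = c(class, "saccadescope_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_invalid_config <- function(msg) abort_sc(msg, "saccadescope_invalid_config")
stop_invalid_input  <- function(msg) abort_sc(msg, "saccadescope_invalid_input")
stop_parse          <- function(msg) abort_sc(msg, "saccadescope_parse_error")

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0

#' Sliding-window means at every possible onset frame
#'
#' For a trace `x` and a window `[a, b]` in frames relative to an onset,
#' returns the window mean for every 0-based onset frame `o` such that the
#' window `o + a .. o + b` lies fully inside the trace; onsets whose window
#' would fall off either end get `NA`. Computed with cumulative sums so the
#' cost is linear in the trace length.
#'
#' @param x numeric trace.
#' @param a,b integer window bounds in frames relative to onset (inclusive;
#'   `a <= b`, may be negative).
#' @return numeric vector of length `length(x)`, element `o + 1` holding the
#'   mean for 0-based onset `o`.
#' @keywords internal
#' @noRd
window_mean_profile <- function(x, a, b) {
  stopifnot(a <= b)
  n <- length(x)
  w <- b - a + 1L
  out <- rep(NA_real_, n)
  cs <- c(0, cumsum(x))
  o <- 0:(n - 1L)
  lo <- o + a          # 0-based first frame of the window
  hi <- o + b
  ok <- lo >= 0L & hi <= n - 1L
  out[ok] <- (cs[hi[ok] + 2L] - cs[lo[ok] + 1L]) / w
  out
}

# Degrees <-> radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Two-sample KS test that tolerates ties (real dF/F and rate data tie
# frequently); exact p-values are not needed at these sample sizes.
ks_p <- function(x, y) {
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}
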