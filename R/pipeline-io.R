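# File formats, run configuration, and the end-to-end pipeline driver.
#
# Formats are deliberately plain text: CSV for gaze traces, saccade event
# tables, epoch tables and dF/F matrices; YAML for run configuration;
# JSON for reports. Missing values are empty CSV fields. All frame
# indices on disk are 0-based, matching the in-memory convention.

#' Write / read a gaze trace as CSV
#'
#' Columns `frame`, `azimuth_deg`, `elevation_deg`; missing frames are
#' empty fields. The frame rate is recorded in a `# frame_rate:` header
#' comment so the round trip is lossless.
#'
#' @param trace a [gaze_trace()].
#' @param path file path.
#' @return `write_gaze_csv` returns `path` invisibly; `read_gaze_csv`
#'   returns a [gaze_trace()].
#' @export
write_gaze_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame_rate: ", frame_rate(trace)), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  fr <- read_header_rate(path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "azimuth_deg", "elevation_deg")
  if (!all(need %in% names(df))) {
    stop_parse(paste0(path, ": gaze CSV must have columns ",
                      paste(need, collapse = ", ")))
  }
  gaze_trace(df$azimuth_deg, df$elevation_deg, fr)
}

read_header_rate <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^# frame_rate: *([0-9.]+)", first))[[1]]
  if (length(m) < 2) {
    stop_parse(paste0(path, ": missing '# frame_rate:' header"))
  }
  as.numeric(m[2])
}

#' Write / read a saccade event table as CSV
#'
#' @param events saccade event data frame (as from [detect_saccades()]).
#' @param path file path.
#' @return `write_saccades_csv` returns `path` invisibly;
#'   `read_saccades_csv` returns the event data frame.
#' @export
write_saccades_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_saccades_csv
#' @export
read_saccades_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_frame", "offset_frame", "magnitude", "direction")
  if (!all(need %in% names(df))) {
    stop_parse(paste0(path, ": saccade CSV lacks required columns (",
                      paste(setdiff(need, names(df)), collapse = ", "), ")"))
  }
  if (any(df$onset_frame >= df$offset_frame)) {
    stop_parse(paste0(path, ": onset_frame must precede offset_frame"))
  }
  df
}

#' Write / read a stimulus-epoch table as CSV
#'
#' Columns `stimulus`, `start_frame` (inclusive, 0-based), `end_frame`
#' (exclusive). Reading enforces non-overlap.
#'
#' @param epochs epoch data frame.
#' @param path file path.
#' @return `write_epochs_csv` returns `path` invisibly; `read_epochs_csv`
#'   returns the epoch data frame ordered by `start_frame`.
#' @export
write_epochs_csv <- function(epochs, path) {
  utils::write.csv(epochs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_epochs_csv
#' @export
read_epochs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus", "start_frame", "end_frame")
  if (!all(need %in% names(df))) {
    stop_parse(paste0(path, ": epochs CSV must have columns ",
                      paste(need, collapse = ", ")))
  }
  if (any(df$end_frame <= df$start_frame)) {
    stop_parse(paste0(path, ": epochs must have end_frame > start_frame"))
  }
  df <- df[order(df$start_frame), , drop = FALSE]
  if (nrow(df) > 1 &&
      any(df$start_frame[-1] < df$end_frame[-nrow(df)])) {
    stop_parse(paste0(path, ": overlapping epochs"))
  }
  rownames(df) <- NULL
  df
}

#' Write / read a dF/F matrix as CSV
#'
#' Stored as a plain numeric matrix, one row per neuron, one column per
#' frame, with a `# frame_rate:` header. `NA` values are empty fields.
#'
#' @param dff neurons x frames matrix with a `frame_rate` attribute.
#' @param path file path.
#' @param n_neurons optional expected neuron count; reading fails if the
#'   file disagrees (alignment check against external metadata).
#' @return `write_dff_csv` returns `path` invisibly; `read_dff_csv`
#'   returns a `dff_matrix`.
#' @export
write_dff_csv <- function(dff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame_rate: ", frame_rate(dff)), con)
  utils::write.table(dff, con, row.names = FALSE, col.names = FALSE,
                     sep = ",", na = "")
  invisible(path)
}

#' @rdname write_dff_csv
#' @export
read_dff_csv <- function(path, n_neurons = NULL) {
  fr <- read_header_rate(path)
  m <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  if (!is.null(n_neurons) && nrow(m) != n_neurons) {
    stop_parse(paste0(path, ": expected ", n_neurons, " neurons, found ",
                      nrow(m)))
  }
  attr(m, "frame_rate") <- fr
  class(m) <- c("dff_matrix", class(m))
  m
}

#' Write an analysis report as JSON
#'
#' @param report a named list of results (numbers, vectors, tables).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run configuration with standard defaults
#'
#' Collects every pipeline threshold with its standard default: the speed
#' floor (10 deg/s), outlier and extension multipliers (3 and 1 sigma),
#' the 300 ms / 3x noise validation rule, the 2 s steady-gaze filter, the
#' 15/15 container and 3/3 spontaneous direction minima, the 8-saccade
#' spontaneous session minimum, 40,000 bootstrap samples at p = 5e-4, the
#' 10% BH false discovery rate and the 0.05 significance level.
#'
#' @param ... overrides of any default field.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    min_speed_floor = 10, n_sigma_outlier = 3, n_sigma_extend = 1,
    noise_window_ms = 300, noise_mult = 3,
    steady_gaze_s = 2, min_nasal = 15, min_temporal = 15,
    min_nasal_spont = 3, min_temporal_spont = 3, min_spont_saccades = 8,
    n_boot = 40000, p_threshold = 5e-4, fdr = 0.10, alpha = 0.05,
    spont_label = "S", seed = 1L,
    # synthetic-session block (used when run_all() simulates its input)
    n_sessions = 1L, duration_s = 1800, frame_rate = 30, saccade_rate = 6,
    burst_prob = 0.335, fixation_noise_sd = 0.08, dropout_rate = 0.02,
    n_neurons = 20L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_invalid_config(paste0("unknown config fields: ",
                               paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The round trip `config -> file -> config` is the identity.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Simulate a complete experiment container
#'
#' Generates 1-3 synthetic sessions sharing one population of neurons:
#' gaze trace with ground-truth saccades, an epoch table from the default
#' eight-stimulus template, and a dF/F matrix realizing the per-neuron
#' response classes.
#'
#' @param config a [run_config()].
#' @param specs list of [neuron_spec()] per neuron, or `NULL` to draw a
#'   default mixture (60% null, 15% enhanced, 10% suppressed, 5% nasal-DS,
#'   10% temporal-DS).
#' @param seed integer seed (defaults to `config$seed`).
#' @return List with `sessions` (each: `trace`, `dff`, `events_truth`,
#'   `epochs`) and `specs`.
#' @export
simulate_container <- function(config = run_config(), specs = NULL,
                               seed = config$seed) {
  n_frames <- round(config$duration_s * config$frame_rate)
  if (is.null(specs)) {
    classes <- local_seed(seed, {
      sample(c("null", "enhanced", "suppressed", "ds_nasal", "ds_temporal"),
             config$n_neurons, replace = TRUE,
             prob = c(0.60, 0.15, 0.10, 0.05, 0.10))
    })
    specs <- lapply(classes, neuron_spec)
  }
  sessions <- lapply(seq_len(config$n_sessions), function(si) {
    sim_cfg <- simulation_config(
      duration_s = config$duration_s, frame_rate = config$frame_rate,
      saccade_rate = config$saccade_rate, burst_prob = config$burst_prob,
      fixation_noise_sd = config$fixation_noise_sd,
      dropout_rate = config$dropout_rate,
      rng_seed = (seed * 1000L + si) %% .Machine$integer.max)
    g <- generate_gaze_trace(sim_cfg)
    epochs <- generate_stimulus_epochs(default_session_template(n_frames),
                                       n_frames)
    dff <- generate_dff(g$ground_truth, specs, n_frames, config$frame_rate,
                        rng_seed = (seed * 1000L + 500L + si) %% .Machine$integer.max)
    list(trace = g$trace, dff = dff, events_truth = g$ground_truth$saccades,
         epochs = epochs)
  })
  list(sessions = sessions, specs = specs)
}

#' Run the full pipeline end to end
#'
#' Chains saccade detection, behavioral summaries, inclusion filtering,
#' SR classification and the modulation screens over one experiment
#' container, returning a structured report. When `container` is `NULL` a
#' synthetic container is simulated from the config, and the report
#' additionally compares recovered classes against the ground truth.
#'
#' @param config a [run_config()].
#' @param container optional list of sessions, each a list with `trace`
#'   (a [gaze_trace()]), `dff` (neurons x frames) and `epochs`.
#' @return A report list: `counts` (saccades at each filter stage, kept
#'   container flag), `behavior` (interval and magnitude summaries),
#'   `classification` (per-neuron data frame), `sr_summary`, and for
#'   synthetic input `recovery` (confusion of true vs recovered classes).
#' @export
run_all <- function(config = run_config(), container = NULL) {
  if (!inherits(config, "run_config")) stop_invalid_config("config must be a run_config")
  truth <- NULL
  specs <- NULL
  if (is.null(container)) {
    sim <- simulate_container(config)
    container <- sim$sessions
    specs <- sim$specs
    truth <- vapply(specs, `[[`, character(1), "true_class")
  }
  if (length(container) == 0) stop_invalid_input("empty container")
  fr <- frame_rate(container[[1]]$dff)

  analysis_sessions <- lapply(container, function(s) {
    ev <- detect_saccades(s$trace, s$epochs,
                          min_speed_floor = config$min_speed_floor,
                          n_sigma_outlier = config$n_sigma_outlier,
                          n_sigma_extend = config$n_sigma_extend,
                          noise_window_ms = config$noise_window_ms,
                          noise_mult = config$noise_mult)
    list(dff = s$dff, events = ev, epochs = s$epochs)
  })
  all_events <- do.call(rbind, lapply(analysis_sessions, `[[`, "events"))
  steady <- do.call(rbind, lapply(analysis_sessions, function(s) {
    steady_gaze_filter(s$events, fr, config$steady_gaze_s)
  }))

  behavior <- list(
    intervals = intersaccade_intervals(all_events, fr),
    magnitude = if (nrow(all_events) > 0) magnitude_asymmetry(all_events) else NULL
  )

  cls <- classify_neurons(
    analysis_sessions, n_boot = config$n_boot, p = config$p_threshold,
    alpha_ds = config$alpha, fdr = config$fdr, seed = config$seed,
    steady_gaze_s = config$steady_gaze_s,
    min_nasal = config$min_nasal, min_temporal = config$min_temporal)

  counts <- list(
    n_sessions = length(container),
    n_detected = nrow(all_events),
    n_steady = nrow(steady),
    container_included = isTRUE(attr(cls, "included")),
    n_neurons = nrow(cls)
  )
  sr <- cls$class %in% c("enhanced", "suppressed")
  sr_summary <- list(
    n_sr = sum(sr, na.rm = TRUE),
    sr_rate_pct = 100 * mean(sr, na.rm = TRUE),
    n_enhanced = sum(cls$class == "enhanced", na.rm = TRUE),
    n_suppressed = sum(cls$class == "suppressed", na.rm = TRUE),
    n_ds = sum(cls$ds, na.rm = TRUE),
    n_modulated = sum(cls$modulated, na.rm = TRUE)
  )
  report <- list(counts = counts, behavior = behavior,
                 classification = cls, sr_summary = sr_summary)
  if (!is.null(truth)) {
    recovered <- recovered_class(cls)
    report$recovery <- list(
      true_class = truth, recovered_class = recovered,
      confusion = table(true = truth, recovered = recovered),
      accuracy = mean(truth == recovered)
    )
  }
  report
}

#' Map a classification row to a ground-truth class label
#'
#' Folds the (class, ds, preferred_direction) triple back onto the
#' generator's label set: `enhanced` + DS-nasal becomes `ds_nasal`, etc.,
#' and `none` maps to `null`.
#'
#' @param cls classification data frame from [classify_neurons()].
#' @return Character vector of recovered labels.
#' @export
recovered_class <- function(cls) {
  out <- character(nrow(cls))
  for (i in seq_len(nrow(cls))) {
    cl <- cls$class[i]
    out[i] <- if (is.na(cl)) {
      NA_character_
    } else if (cl == "none") {
      "null"
    } else if (cl == "enhanced" && isTRUE(cls$ds[i])) {
      if (cls$preferred_direction[i] == "nasal") "ds_nasal" else "ds_temporal"
    } else cl
  }
  out
}
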