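#' Fast-SMT mobility pipeline
#'
#' Runs detect -> link -> filter -> mobility analysis on a fast-regime
#' (short-exposure) movie, or on pre-tracked input (a [trajectory_set()]),
#' in which case detection and linking are skipped.
#'
#' @param input A [movie_stack()] or a [trajectory_set()].
#' @param filter_cfg A [filter_config()].
#' @param mobility_cfg A [mobility_config()].
#' @param max_disp Linking gate, um/frame (default 0.8, consistent with a
#'   maximum expected D of ~10 um^2/s at a 20 ms interval).
#' @param max_gap Linking gap closing, frames (default 0 in the fast
#'   regime).
#' @param detect_args List of extra arguments for [detect_stack()].
#' @return A list of class `smt_report`: `summary` (a
#'   [mobility_summary()]), `tracks`, `provenance`.
#' @export
run_fast_smt <- function(input, filter_cfg = filter_config(),
                         mobility_cfg = mobility_config(),
                         max_disp = 0.8, max_gap = 0, detect_args = list()) {
  ts <- pipeline_tracks(input, max_disp, max_gap, "fast", detect_args)
  if (n_tracks(ts) == 0) abort("no trajectories found in input")
  filtered <- filter_fast_tracks(ts, filter_cfg)
  if (n_tracks(filtered) == 0) abort("no trajectories survive the filters")
  structure(list(summary = mobility_summary(filtered, mobility_cfg),
                 tracks = filtered,
                 provenance = attr(filtered, "provenance")),
            class = "smt_report")
}

#' Slow-SMT residence-time pipeline
#'
#' Runs detect -> link -> bound-molecule filter -> survival construction ->
#' low-count truncation -> photobleach correction -> model fitting (2- and
#' 3-component exponential mixtures and the power law) -> BIC selection.
#' The bleaching rate comes either from `k_bleach` directly or from a
#' control duration set (e.g. H2B) via [calibrate_bleach()].
#'
#' @param input A [movie_stack()] or slow-regime [trajectory_set()].
#' @param k_bleach Bleaching rate, 1/s; alternative to `control_durations`.
#' @param control_durations Durations (s) of a stably bound control used to
#'   calibrate bleaching when `k_bleach` is `NULL`.
#' @param filter_cfg A [filter_config()] (bound-molecule D cutoff).
#' @param min_events Low-count truncation threshold (0 keeps all points).
#' @param max_disp Linking gate, um/frame (default 0.45, a 3-sigma gate for
#'   D = 0.1 um^2/s at a 500 ms interval).
#' @param max_gap Linking gap closing, frames (default 1 in the slow
#'   regime: long binders suffer single-frame detection dropouts).
#' @param n_boot Bootstrap replicates for parameter CIs.
#' @param seed Seed for the bootstrap.
#' @param detect_args List of extra arguments for [detect_stack()].
#' @return A list of class `dwell_report`: `survival` (corrected), `fits`,
#'   `selection`, `dwell_summary` (from the 2-component fit), `k_bleach`,
#'   `calibration` (if computed), `provenance`.
#' @export
run_slow_smt <- function(input, k_bleach = NULL, control_durations = NULL,
                         filter_cfg = filter_config(), min_events = 30,
                         max_disp = 0.45, max_gap = 1,
                         n_boot = 200, seed = 1, detect_args = list()) {
  ts <- pipeline_tracks(input, max_disp, max_gap, "slow", detect_args)
  if (n_tracks(ts) == 0) abort("no trajectories found in input")
  filtered <- filter_slow_tracks(ts, filter_cfg)
  if (n_tracks(filtered) == 0) abort("no bound trajectories survive the filter")
  dt <- attr(filtered, "frame_interval")
  durations <- track_summary(filtered)$duration_s

  calibration <- NULL
  if (is.null(k_bleach)) {
    if (is.null(control_durations))
      abort("supply `k_bleach` or `control_durations` for bleach correction")
    ctrl <- truncate_low_counts(build_survival(control_durations, dt),
                                min_events)
    calibration <- calibrate_bleach(ctrl)
    k_bleach <- calibration$k_bleach
  }

  surv <- build_survival(durations, dt)
  surv <- truncate_low_counts(surv, min_events)
  surv <- bleach_correct(surv, k_bleach)

  fits <- list(
    exp_2 = fit_exp_mixture(surv, 2, n_boot = n_boot, seed = seed),
    exp_3 = fit_exp_mixture(surv, 3, n_boot = 0),
    power_law = tryCatch(fit_power_law(surv, n_boot = n_boot, seed = seed),
                         error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  ok <- !vapply(fits, function(f) isTRUE(f$failed), logical(1))
  selection <- if (sum(ok) >= 2) select_model(fits[ok]) else NULL
  dwell_summary <- if (!isTRUE(fits$exp_2$failed))
    summarize_dwell(fits$exp_2) else NULL

  structure(list(survival = surv, fits = fits, selection = selection,
                 dwell_summary = dwell_summary, k_bleach = k_bleach,
                 calibration = calibration, n_durations = length(durations),
                 provenance = attr(filtered, "provenance")),
            class = "dwell_report")
}

#' RICS pipeline
#'
#' Runs moving-average subtraction -> spatial autocorrelation ->
#' one-component diffusion fit on a raster-scan series.
#'
#' @param movie A [movie_stack()] with scan metadata (`pixel_dwell`,
#'   `line_time`) attached.
#' @param w0,wz Beam waist calibration, um.
#' @param window Moving-average window, frames.
#' @param fit_xi,fit_psi Fit-domain radii, pixels.
#' @return A list of class `rics_report`: `fit`, `acf`.
#' @export
run_rics <- function(movie, w0 = 0.25, wz = 1.5, window = 10,
                     fit_xi = 32, fit_psi = 8) {
  if (is.null(attr(movie, "scan")))
    abort("scan metadata (pixel_dwell, line_time) required")
  detrended <- moving_average_subtract(movie, window)
  acf <- compute_acf(detrended)
  fit <- fit_one_component(acf, w0 = w0, wz = wz,
                           fit_xi = fit_xi, fit_psi = fit_psi)
  structure(list(fit = fit, acf = acf), class = "rics_report")
}

# movie -> detected + linked tracks; trajectory_set passes through
pipeline_tracks <- function(input, max_disp, max_gap, regime, detect_args) {
  if (inherits(input, "trajectory_set")) return(input)
  if (!inherits(input, "movie_stack"))
    abort("`input` must be a movie_stack or trajectory_set")
  if (is.null(attr(input, "pixel_size")) || is.null(attr(input, "frame_interval")))
    abort("movie calibration (pixel_size, frame_interval) required")
  locs <- do.call(detect_stack, c(list(input), detect_args))
  if (nrow(locs) == 0) abort("no particles detected")
  link_trajectories(locs, max_disp = max_disp, max_gap = max_gap,
                    pixel_size = attr(input, "pixel_size"),
                    frame_interval = attr(input, "frame_interval"),
                    regime = regime)
}

#' @export
print.smt_report <- function(x, ...) {
  cat("Fast-SMT report\n")
  print(x$summary)
  print(x$provenance)
  invisible(x)
}

#' @export
print.dwell_report <- function(x, ...) {
  cat(sprintf("Slow-SMT dwell report (%d durations, k_bleach = %.4g /s)\n",
              x$n_durations, x$k_bleach))
  if (!is.null(x$selection)) print(x$selection)
  if (!is.null(x$dwell_summary))
    cat(sprintf("2-exp summary: tau_long = %.3g s, tau_short = %.3g s, f_long = %.3f\n",
                x$dwell_summary$tau_long, x$dwell_summary$tau_short,
                x$dwell_summary$f_long))
  invisible(x)
}

#' @export
print.rics_report <- function(x, ...) {
  cat("RICS report\n")
  print(x$fit)
  invisible(x)
}
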