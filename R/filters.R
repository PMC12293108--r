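#' Trajectory filter settings
#'
#' Defaults are the standard fast-SMT filters (minimum length 8 frames,
#' maximum length 1000 frames, maximum travel 5 um from the starting
#' position) and the slow-SMT bound-molecule criterion (maximum expected
#' diffusion coefficient 0.1 um^2/s).
#'
#' @param min_length Minimum track length, frames (>= 2).
#' @param max_length Maximum track length, frames.
#' @param max_travel Maximum displacement from the first position, um.
#' @param d_max_slow Maximum diffusion coefficient for slow-regime (bound)
#'   tracks, um^2/s.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_length = 8, max_length = 1000,
                          max_travel = 5, d_max_slow = 0.1) {
  if (min_length < 2) abort("`min_length` must be >= 2")
  stop_if_not_positive(max_travel, "max_travel")
  if (max_length < min_length) abort("`max_length` must be >= `min_length`")
  structure(list(min_length = min_length, max_length = max_length,
                 max_travel = max_travel, d_max_slow = d_max_slow),
            class = "filter_config")
}

#' Filter fast-regime trajectories
#'
#' Keeps tracks whose length (frames) lies in `[min_length, max_length]` and
#' whose maximum displacement from the starting position is at most
#' `max_travel`. Before/after counts are appended to the provenance log.
#'
#' @param ts A [trajectory_set()].
#' @param cfg A [filter_config()].
#' @return A filtered [trajectory_set()].
#' @export
filter_fast_tracks <- function(ts, cfg = filter_config()) {
  ss <- track_summary(ts)
  keep <- ss$track_id[ss$n_frames >= cfg$min_length &
                      ss$n_frames <= cfg$max_length &
                      ss$max_span_um <= cfg$max_travel]
  reset_tracks(ts, dplyr::filter(as_tibble(ts), .data$track_id %in% keep),
               "filter_fast",
               sprintf("length in [%d, %d], travel <= %g um",
                       cfg$min_length, cfg$max_length, cfg$max_travel))
}

#' Filter slow-regime trajectories by apparent diffusion coefficient
#'
#' Estimates each track's diffusion coefficient (MSD fit, see
#' [estimate_track_diffusion()]) and keeps tracks with `D <= d_max_slow`,
#' isolating bound molecules. Tracks too short for the MSD fit are dropped
#' (kept if `keep_short = TRUE`); either way the attrition is logged.
#'
#' @param ts A [trajectory_set()].
#' @param cfg A [filter_config()].
#' @param n_fit_points Number of MSD lags used in the D fit.
#' @param keep_short Keep tracks too short for D estimation?
#' @return A filtered [trajectory_set()].
#' @export
filter_slow_tracks <- function(ts, cfg = filter_config(),
                               n_fit_points = 4, keep_short = FALSE) {
  dd <- track_diffusion(ts, n_fit_points = n_fit_points)
  short <- dd$track_id[is.na(dd$d)]
  keep <- dd$track_id[!is.na(dd$d) & dd$d <= cfg$d_max_slow]
  if (keep_short) keep <- c(keep, short)
  reset_tracks(ts, dplyr::filter(as_tibble(ts), .data$track_id %in% keep),
               "filter_slow",
               sprintf("D <= %g um^2/s; %d short tracks %s", cfg$d_max_slow,
                       length(short), if (keep_short) "kept" else "dropped"))
}

#' Split trajectories by a binary region mask
#'
#' A track is "inside" (e.g. within a nuclear condensate) if at least
#' `min_inside_fraction` of its localizations fall on mask-true pixels.
#'
#' @param ts A [trajectory_set()].
#' @param mask Logical matrix (y, x) on the movie pixel grid.
#' @param min_inside_fraction Fraction of localizations required inside.
#' @return A list with [trajectory_set()] elements `inside` and `outside`.
#' @export
split_by_mask <- function(ts, mask, min_inside_fraction = 0.5) {
  px <- attr(ts, "pixel_size")
  ci <- pmin(pmax(floor(ts$x_um / px) + 1L, 1L), ncol(mask))
  ri <- pmin(pmax(floor(ts$y_um / px) + 1L, 1L), nrow(mask))
  inside_pt <- mask[cbind(ri, ci)]
  frac <- tapply(inside_pt, ts$track_id, mean)
  in_ids <- as.integer(names(frac))[frac >= min_inside_fraction]
  tb <- as_tibble(ts)
  list(
    inside = reset_tracks(ts, dplyr::filter(tb, .data$track_id %in% in_ids),
                          "split_by_mask", "inside"),
    outside = reset_tracks(ts, dplyr::filter(tb, !.data$track_id %in% in_ids),
                           "split_by_mask", "outside"))
}
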