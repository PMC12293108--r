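#' Trajectory sets
#'
#' A `trajectory_set` is a tibble of localizations (one row per molecule per
#' frame) carrying acquisition metadata as attributes. Columns: `track_id`,
#' `frame` (0-based), `x_um`, `y_um`, and optionally `intensity` and `state`.
#' Physical coordinates are in micrometers with the origin at the image
#' corner; the center of pixel `i` (0-based) is at `(i + 0.5) * pixel_size`.
#'
#' @param locs A data frame of localizations with at least `track_id`,
#'   `frame`, `x_um`, `y_um`.
#' @param pixel_size Pixel size, um.
#' @param frame_interval Frame interval, s.
#' @param regime Acquisition regime: `"fast"`, `"slow"`, or `NA`.
#' @param provenance Optional tibble logging processing stages.
#' @return A tibble with class `trajectory_set`.
#' @export
trajectory_set <- function(locs, pixel_size, frame_interval,
                           regime = NA_character_, provenance = NULL) {
  stop_if_not_positive(pixel_size, "pixel_size")
  stop_if_not_positive(frame_interval, "frame_interval")
  locs <- as_tibble(locs)
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(locs)))
    abort(paste("localizations need columns:", paste(need, collapse = ", ")))
  locs <- dplyr::arrange(locs, .data$track_id, .data$frame)
  if (is.null(provenance))
    provenance <- tibble(stage = character(), n_tracks_in = integer(),
                         n_tracks_out = integer(), note = character())
  structure(locs,
            class = c("trajectory_set", class(tibble())),
            pixel_size = pixel_size, frame_interval = frame_interval,
            regime = regime, provenance = provenance)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set: %d tracks, %d localizations, regime=%s, dt=%gs, px=%gum>\n",
              n_tracks(x), nrow(x), attr(x, "regime"),
              attr(x, "frame_interval"), attr(x, "pixel_size")))
  NextMethod()
}

#' Number of tracks in a trajectory set
#' @param ts A [trajectory_set()].
#' @return Integer count of distinct track ids.
#' @export
n_tracks <- function(ts) length(unique(ts$track_id))

#' Per-track duration and geometry summaries
#'
#' @param ts A [trajectory_set()].
#' @return A tibble with one row per track: `track_id`, `n_frames`
#'   (localizations), `duration_s` (`n_frames * frame_interval`: a molecule
#'   present for k frames was present for at least k frame intervals),
#'   `max_span_um` (maximum displacement from the track's first position).
#' @export
track_summary <- function(ts) {
  dt <- attr(ts, "frame_interval")
  dplyr::summarise(
    dplyr::group_by(as_tibble(ts), .data$track_id),
    n_frames = dplyr::n(),
    duration_s = dplyr::n() * dt,
    max_span_um = {
      dx <- .data$x_um - .data$x_um[1]
      dy <- .data$y_um - .data$y_um[1]
      sqrt(max(dx^2 + dy^2))
    },
    .groups = "drop"
  )
}

# rebuild a trajectory_set after row filtering, appending a provenance entry
reset_tracks <- function(ts, locs, stage, note = "") {
  prov <- attr(ts, "provenance")
  out <- trajectory_set(locs,
                        pixel_size = attr(ts, "pixel_size"),
                        frame_interval = attr(ts, "frame_interval"),
                        regime = attr(ts, "regime"),
                        provenance = dplyr::bind_rows(
                          prov,
                          tibble(stage = stage,
                                 n_tracks_in = n_tracks(ts),
                                 n_tracks_out = length(unique(locs$track_id)),
                                 note = note)))
  out
}

#' Convert between physical and pixel coordinates
#'
#' Pixel indices are 0-based; the center of pixel `i` is at
#' `(i + 0.5) * pixel_size` um, so the two functions are exact inverses.
#'
#' @param x_um,x_px Coordinates in um / fractional pixels.
#' @param pixel_size Pixel size, um.
#' @return Numeric vector of converted coordinates.
#' @export
um_to_px <- function(x_um, pixel_size) x_um / pixel_size - 0.5

#' @rdname um_to_px
#' @export
px_to_um <- function(x_px, pixel_size) (x_px + 0.5) * pixel_size

#' Read and write trajectory CSV files
#'
#' The on-disk format has columns `track_id, frame, x_um, y_um` plus optional
#' `intensity` and `state`.
#'
#' @param ts A [trajectory_set()].
#' @param path File path.
#' @param pixel_size,frame_interval,regime Acquisition metadata to attach on
#'   read (the CSV itself stores only the table).
#' @return `write_tracks_csv()` returns `path` invisibly;
#'   `read_tracks_csv()` returns a [trajectory_set()].
#' @export
write_tracks_csv <- function(ts, path) {
  write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, pixel_size, frame_interval,
                            regime = NA_character_) {
  trajectory_set(read.csv(path), pixel_size = pixel_size,
                 frame_interval = frame_interval, regime = regime)
}
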