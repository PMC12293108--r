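#' Link per-frame localizations into trajectories
#'
#' Greedy nearest-neighbor assignment between consecutive frames with a hard
#' distance gate: candidate (track, localization) pairs are linked in order
#' of increasing distance, each partner used at most once, and only if the
#' displacement is at most `max_disp`. A track not extended for more than
#' `max_gap` consecutive frames is terminated; unassigned localizations
#' start new tracks. At the low emitter densities required for
#' single-molecule imaging this coincides with full multiple-target tracing.
#'
#' @param locs A tibble of localizations with columns `frame` (0-based),
#'   `x_um`, `y_um`, optionally `intensity`.
#' @param max_disp Maximum per-link displacement, um.
#' @param max_gap Maximum number of consecutive missed frames bridged.
#' @param pixel_size Pixel size, um.
#' @param frame_interval Frame interval, s.
#' @param regime Acquisition regime label (`"fast"` or `"slow"`).
#' @return A [trajectory_set()].
#' @export
link_trajectories <- function(locs, max_disp, max_gap = 0,
                              pixel_size, frame_interval,
                              regime = NA_character_) {
  if (max_disp <= 0 || max_gap < 0) abort("gates must be positive")
  locs <- as_tibble(locs)
  if (nrow(locs) == 0)
    return(trajectory_set(tibble(track_id = integer(), frame = integer(),
                                 x_um = numeric(), y_um = numeric()),
                          pixel_size, frame_interval, regime))
  locs <- dplyr::arrange(locs, .data$frame)
  frames <- sort(unique(locs$frame))
  by_frame <- split(seq_len(nrow(locs)), locs$frame)

  track_id <- integer(nrow(locs))
  next_id <- 1L
  # active tracks: id, x, y, last frame
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0)

  for (f in frames) {
    keep <- (f - act_f) <= (max_gap + 1L)
    act_id <- act_id[keep]; act_x <- act_x[keep]
    act_y <- act_y[keep]; act_f <- act_f[keep]
    idx <- by_frame[[as.character(f)]]
    nx <- locs$x_um[idx]; ny <- locs$y_um[idx]
    assigned <- rep(FALSE, length(idx))
    if (length(act_id) > 0 && length(idx) > 0) {
      d <- sqrt(outer(act_x, nx, "-")^2 + outer(act_y, ny, "-")^2)
      d[d > max_disp] <- Inf
      used_t <- rep(FALSE, length(act_id))
      repeat {
        m <- which.min(d)
        if (length(m) == 0 || !is.finite(d[m])) break
        ti <- (m - 1L) %% length(act_id) + 1L
        li <- (m - 1L) %/% length(act_id) + 1L
        track_id[idx[li]] <- act_id[ti]
        act_x[ti] <- nx[li]; act_y[ti] <- ny[li]; act_f[ti] <- f
        used_t[ti] <- TRUE; assigned[li] <- TRUE
        d[ti, ] <- Inf; d[, li] <- Inf
        if (all(used_t) || all(assigned)) break
      }
    }
    if (any(!assigned)) {
      n_new <- sum(!assigned)
      ids <- seq.int(next_id, length.out = n_new)
      track_id[idx[!assigned]] <- ids
      act_id <- c(act_id, ids)
      act_x <- c(act_x, nx[!assigned]); act_y <- c(act_y, ny[!assigned])
      act_f <- c(act_f, rep(f, n_new))
      next_id <- next_id + n_new
    }
  }
  locs$track_id <- track_id
  keep_cols <- intersect(c("track_id", "frame", "x_um", "y_um", "intensity"),
                         names(locs))
  trajectory_set(locs[keep_cols], pixel_size, frame_interval, regime)
}
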