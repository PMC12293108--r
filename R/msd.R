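#' Time-averaged mean squared displacement of one track
#'
#' MSD at lag `k * dt` is the mean of `|r(i+k) - r(i)|^2` over all
#' overlapping position pairs in the track (standard time-averaged
#' single-particle-tracking estimator; overlapping pairs maximize the
#' information in short tracks).
#'
#' @param track A data frame with columns `x_um`, `y_um` (time-ordered,
#'   consecutive frames), or a [trajectory_set()] containing one track.
#' @param frame_interval Frame interval, s (taken from the trajectory set if
#'   available).
#' @param max_lag_points Number of lags to report; truncated with a warning
#'   when the track is too short.
#' @return A tibble of class `msd_curve` with columns `lag_s`, `msd`
#'   (um^2), `n_pairs`.
#' @export
compute_msd <- function(track, frame_interval = NULL, max_lag_points = 10) {
  if (is.null(frame_interval)) frame_interval <- attr(track, "frame_interval")
  if (is.null(frame_interval)) abort("`frame_interval` required")
  n <- nrow(track)
  if (n < 2) abort("track must have >= 2 positions")
  if (max_lag_points >= n) {
    warn(sprintf("max_lag_points %d >= track length %d; truncating",
                 max_lag_points, n))
    max_lag_points <- n - 1L
  }
  x <- track$x_um; y <- track$y_um
  lags <- seq_len(max_lag_points)
  msd <- vapply(lags, function(k) {
    i <- seq_len(n - k)
    mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  }, numeric(1))
  out <- tibble(lag_s = lags * frame_interval, msd = msd, n_pairs = n - lags)
  class(out) <- c("msd_curve", class(out))
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Unweighted linear least-squares fit of `MSD(tau) = 4 D tau + b` over the
#' first `n_fit_points` lags; the intercept absorbs the localization-error
#' offset. `D` may be negative for noise-dominated immobile tracks
#' (excluded downstream from histograms and classification).
#'
#' @param msd An [compute_msd()] result (or any tibble with `lag_s`, `msd`).
#' @param n_fit_points Number of leading lags used.
#' @return A list with `d` (um^2/s) and `intercept` (um^2).
#' @export
estimate_track_diffusion <- function(msd, n_fit_points = 4) {
  if (nrow(msd) < n_fit_points)
    abort(sprintf("need >= %d MSD points, have %d", n_fit_points, nrow(msd)))
  m <- msd[seq_len(n_fit_points), ]
  if (all(m$msd == m$msd[1]))
    return(list(d = 0, intercept = m$msd[1]))
  fit <- lm(msd ~ lag_s, data = m)
  list(d = unname(coef(fit)[2]) / 4, intercept = unname(coef(fit)[1]))
}

#' Per-track diffusion coefficients for a trajectory set
#'
#' @param ts A [trajectory_set()].
#' @param n_fit_points Lags used in each per-track fit.
#' @param max_lag_points MSD lags computed per track.
#' @return A tibble: `track_id`, `n_frames`, `d` (um^2/s; `NA` for tracks
#'   shorter than `n_fit_points + 1`), `log10_d` (`NA` for `d <= 0`).
#' @export
track_diffusion <- function(ts, n_fit_points = 4, max_lag_points = 10) {
  dt <- attr(ts, "frame_interval")
  tb <- as_tibble(ts)
  res <- dplyr::group_by(tb, .data$track_id)
  res <- dplyr::summarise(res, n_frames = dplyr::n(), d = {
    if (dplyr::n() < n_fit_points + 1) NA_real_ else {
      m <- compute_msd(dplyr::pick(dplyr::everything()), frame_interval = dt,
                       max_lag_points = min(max_lag_points, dplyr::n() - 1L))
      estimate_track_diffusion(m, n_fit_points)$d
    }
  }, .groups = "drop")
  res$log10_d <- NA_real_
  pos <- !is.na(res$d) & res$d > 0
  res$log10_d[pos] <- log10(res$d[pos])
  res
}
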