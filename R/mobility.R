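#' Fast-SMT mobility analysis settings
#'
#' Defaults are the standard fast-SMT analysis values: 10 MSD points at a
#' 0.02 s interval, log10 D range [-5, 1] with 0.1-wide bins, a
#' mobile/immobile threshold of -1.45 (~0.035 um^2/s on the linear scale),
#' and a 4-point MSD fit for the per-track diffusion coefficient.
#'
#' @param n_msd_points MSD lags computed per track.
#' @param msd_time_interval Frame interval for MSD lags, s.
#' @param log10_d_min,log10_d_max Included range of log10 D.
#' @param bin_width Histogram bin width in log10 D.
#' @param mobile_threshold_log10 Classification threshold on log10 D.
#' @param n_fit_points Lags used in the per-track D fit.
#' @return An object of class `mobility_config`.
#' @export
mobility_config <- function(n_msd_points = 10, msd_time_interval = 0.02,
                            log10_d_min = -5, log10_d_max = 1,
                            bin_width = 0.1, mobile_threshold_log10 = -1.45,
                            n_fit_points = 4) {
  if (!(log10_d_min < mobile_threshold_log10 &&
        mobile_threshold_log10 < log10_d_max))
    abort("need log10_d_min < mobile_threshold_log10 < log10_d_max")
  stop_if_not_positive(bin_width, "bin_width")
  structure(list(n_msd_points = n_msd_points,
                 msd_time_interval = msd_time_interval,
                 log10_d_min = log10_d_min, log10_d_max = log10_d_max,
                 bin_width = bin_width,
                 mobile_threshold_log10 = mobile_threshold_log10,
                 n_fit_points = n_fit_points),
            class = "mobility_config")
}

#' Normalized log10 diffusion-coefficient histogram
#'
#' Non-positive D values and values outside `[10^log10_d_min,
#' 10^log10_d_max]` are excluded (counts recorded in attributes);
#' frequencies are normalized to sum to 1.
#'
#' @param d_values Per-track diffusion coefficients, um^2/s.
#' @param cfg A [mobility_config()].
#' @return A tibble `(bin_mid, freq, count)` of class `mobility_histogram`
#'   with attributes `n_used`, `n_excluded_nonpositive`,
#'   `n_excluded_range`.
#' @export
mobility_distribution <- function(d_values, cfg = mobility_config()) {
  d_values <- d_values[!is.na(d_values)]
  n_nonpos <- sum(d_values <= 0)
  ld <- log10(d_values[d_values > 0])
  in_range <- ld >= cfg$log10_d_min & ld <= cfg$log10_d_max
  n_range <- sum(!in_range)
  ld <- ld[in_range]
  if (length(ld) == 0) abort("no tracks within the log10 D range")
  breaks <- seq(cfg$log10_d_min, cfg$log10_d_max + cfg$bin_width,
                by = cfg$bin_width)
  cnt <- table(cut(ld, breaks, right = FALSE, include.lowest = TRUE))
  out <- tibble(bin_mid = head(breaks, -1) + cfg$bin_width / 2,
                freq = as.numeric(cnt) / length(ld),
                count = as.integer(cnt))
  structure(out, class = c("mobility_histogram", class(tibble())),
            n_used = length(ld), n_excluded_nonpositive = n_nonpos,
            n_excluded_range = n_range,
            mobile_threshold_log10 = cfg$mobile_threshold_log10)
}

#' Classify tracks as mobile or immobile
#'
#' Tracks with `log10 D` above the threshold are mobile. The threshold's
#' linear-scale equivalent (`10^threshold`, ~0.035 um^2/s at -1.45) is
#' returned alongside the mobile fraction and the mobile:immobile count
#' ratio.
#'
#' @param d_values Per-track diffusion coefficients, um^2/s; non-positive
#'   and out-of-range values are excluded as in [mobility_distribution()].
#' @param threshold_log10 Classification threshold on log10 D.
#' @param cfg A [mobility_config()] supplying the included range.
#' @return A list: `mobile_fraction`, `ratio` (`Inf` when no track is
#'   immobile), `n_mobile`, `n_immobile`, `threshold_linear` (um^2/s).
#' @export
classify_mobile_immobile <- function(d_values,
                                     threshold_log10 = -1.45,
                                     cfg = mobility_config()) {
  d_values <- d_values[!is.na(d_values) & d_values > 0]
  ld <- log10(d_values)
  ld <- ld[ld >= cfg$log10_d_min & ld <= cfg$log10_d_max]
  if (length(ld) == 0) abort("no tracks within the log10 D range")
  n_mob <- sum(ld > threshold_log10)
  n_imm <- length(ld) - n_mob
  list(mobile_fraction = n_mob / length(ld),
       ratio = if (n_imm > 0) n_mob / n_imm else Inf,
       n_mobile = n_mob, n_immobile = n_imm,
       threshold_linear = 10^threshold_log10)
}

#' Ensemble MSD and its area under the curve
#'
#' Averages per-track MSD values at the first `n_msd_points` lags over all
#' tracks of one cell (tracks shorter than the full lag range contribute
#' their available lags; per-lag track counts are reported) and integrates
#' the mean curve by the trapezoidal rule, giving the AUC summary of how
#' far the population moves in the analyzed time window.
#'
#' @param ts A filtered fast-regime [trajectory_set()].
#' @param cfg A [mobility_config()].
#' @return A list: `msd` (tibble `lag_s`, `msd`, `n_tracks`), `auc`
#'   (um^2 s).
#' @export
ensemble_msd_and_auc <- function(ts, cfg = mobility_config()) {
  dt <- attr(ts, "frame_interval")
  tb <- as_tibble(ts)
  per_track <- lapply(split(tb, tb$track_id), function(tr) {
    if (nrow(tr) < 2) return(NULL)
    compute_msd(tr, frame_interval = dt,
                max_lag_points = min(cfg$n_msd_points, nrow(tr) - 1L))
  })
  all_msd <- dplyr::bind_rows(per_track)
  if (nrow(all_msd) == 0) abort("no tracks long enough for MSD")
  mean_msd <- dplyr::summarise(dplyr::group_by(all_msd, .data$lag_s),
                               msd = mean(.data$msd),
                               n_tracks = dplyr::n(), .groups = "drop")
  mean_msd <- dplyr::arrange(mean_msd, .data$lag_s)
  auc <- trapz_auc(mean_msd$lag_s, mean_msd$msd)
  list(msd = mean_msd, auc = auc)
}

trapz_auc <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Per-cell mobility summary
#'
#' Runs the full fast-SMT mobility analysis on one cell's (filtered)
#' trajectory set: per-track diffusion coefficients, the normalized log10 D
#' histogram, mobile/immobile classification, the ensemble MSD and its AUC.
#'
#' @param ts A filtered fast-regime [trajectory_set()].
#' @param cfg A [mobility_config()].
#' @return An object of class `mobility_summary`.
#' @export
mobility_summary <- function(ts, cfg = mobility_config()) {
  dd <- track_diffusion(ts, n_fit_points = cfg$n_fit_points,
                        max_lag_points = cfg$n_msd_points)
  hist <- mobility_distribution(dd$d, cfg)
  cls <- classify_mobile_immobile(dd$d, cfg$mobile_threshold_log10, cfg)
  ens <- ensemble_msd_and_auc(ts, cfg)
  structure(list(d_values = dd, histogram = hist, classification = cls,
                 ensemble_msd = ens$msd, auc = ens$auc, config = cfg),
            class = "mobility_summary")
}

#' @export
print.mobility_summary <- function(x, ...) {
  cat(sprintf(paste0("<mobility_summary: %d tracks, mobile fraction %.3f, ",
                     "mobile:immobile %.2f, AUC %.4g um^2 s>\n"),
              nrow(x$d_values), x$classification$mobile_fraction,
              x$classification$ratio, x$auc))
  invisible(x)
}

#' @method tidy mobility_summary
#' @export
tidy.mobility_summary <- function(x, ...) {
  tibble(bin_mid = x$histogram$bin_mid, freq = x$histogram$freq,
         count = x$histogram$count)
}

#' @method glance mobility_summary
#' @export
glance.mobility_summary <- function(x, ...) {
  tibble(n_tracks = nrow(x$d_values),
         mobile_fraction = x$classification$mobile_fraction,
         mobile_immobile_ratio = x$classification$ratio,
         auc_um2_s = x$auc,
         median_d = median(x$d_values$d, na.rm = TRUE))
}

#' @method autoplot mobility_summary
#' @export
autoplot.mobility_summary <- function(object, ...) {
  thr <- object$config$mobile_threshold_log10
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$bin_mid, y = .data$freq)) +
    ggplot2::geom_col(width = object$config$bin_width, fill = "grey40") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = expression(log[10] ~ D ~ (mu * m^2 / s)),
                  y = "Frequency") +
    ggplot2::theme_classic()
}

#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$msd)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Lag time (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_classic()
}
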