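#' Empirical survival distribution of dwell durations
#'
#' Builds the complement-CDF of observed (frame-discretized) durations:
#' `S(t) = #{durations >= t} / n` evaluated at every multiple of the frame
#' interval up to the longest duration, together with the cumulative event
#' counts used for low-count truncation. The durations themselves are kept
#' as an attribute so bootstrap resampling can replay the full
#' truncate/correct/fit chain.
#'
#' @param durations Observed durations, s (multiples of `frame_interval`).
#' @param frame_interval Frame interval, s.
#' @return A tibble of class `survival_dist` with columns `time`,
#'   `survival`, `events_remaining`; attributes `n_total`, `dt`,
#'   `durations`.
#' @examples
#' build_survival(c(1, 1, 2, 4) * 0.5, 0.5)
#' @export
build_survival <- function(durations, frame_interval) {
  stop_if_not_positive(frame_interval, "frame_interval")
  if (length(durations) == 0) abort("empty duration list")
  frames <- round(durations / frame_interval)
  if (any(frames < 1) || any(abs(frames * frame_interval - durations) >
                             1e-6 * frame_interval))
    abort("durations must be positive multiples of `frame_interval`")
  kmax <- max(frames)
  cnt <- tabulate(frames, nbins = kmax)
  remaining <- rev(cumsum(rev(cnt)))  # events with duration >= k frames
  out <- tibble(time = seq_len(kmax) * frame_interval,
                survival = remaining / length(durations),
                events_remaining = as.integer(remaining))
  structure(out, class = c("survival_dist", class(tibble())),
            n_total = length(durations), dt = frame_interval,
            durations = durations, min_events = 0L, k_bleach = 0)
}

survival_attrs <- function(surv) {
  attributes(surv)[c("n_total", "dt", "durations", "min_events", "k_bleach")]
}

restore_survival <- function(tb, template, ...) {
  at <- survival_attrs(template)
  dots <- list(...)
  at[names(dots)] <- dots
  structure(tb, class = c("survival_dist", class(tibble())),
            n_total = at$n_total, dt = at$dt, durations = at$durations,
            min_events = at$min_events, k_bleach = at$k_bleach)
}

#' Drop low-count time points from a survival distribution
#'
#' Time points with fewer than `min_events` cumulative events remaining are
#' excluded from fitting (default 30); `min_events = 0` keeps every point
#' (the all-points mode used for paired analyses on small track sets).
#'
#' @param surv A [build_survival()] result.
#' @param min_events Minimum cumulative events per retained time point.
#' @return A truncated `survival_dist`.
#' @export
truncate_low_counts <- function(surv, min_events = 30) {
  if (!inherits(surv, "survival_dist")) abort("`surv` must be a survival_dist")
  keep <- surv$events_remaining >= min_events
  if (!any(keep)) abort("all time points fall below `min_events`")
  restore_survival(as_tibble(surv)[keep, ], surv,
                   min_events = as.integer(min_events))
}

#' Photobleach-correct a survival distribution
#'
#' Multiplies the observed survival by `exp(k_bleach * (t - t1))` (t1 the
#' first time point) and renormalizes so the corrected curve starts at 1.
#' When bleaching and unbinding compete as independent exponentials this
#' exactly removes the bleaching contribution. Corrected values that
#' *increase* with time indicate over-correction and are flagged (attribute
#' `n_monotonicity_violations`), never silently clipped.
#'
#' @param surv A `survival_dist` (typically after [truncate_low_counts()]).
#' @param k_bleach Bleaching rate, 1/s (from [calibrate_bleach()]).
#' @return The corrected `survival_dist`; `k_bleach` is recorded so
#'   bootstrap replicates apply the same correction.
#' @export
bleach_correct <- function(surv, k_bleach) {
  if (!inherits(surv, "survival_dist")) abort("`surv` must be a survival_dist")
  stop_if_not_scalar_number(k_bleach, "k_bleach", lower = 0)
  t1 <- surv$time[1]
  s <- surv$survival * exp(k_bleach * (surv$time - t1))
  s <- s / s[1]
  n_viol <- sum(diff(s) > 1e-9)
  rise <- sum(pmax(diff(s), 0))
  if (rise > 0.1 || max(s) > 1.02)
    warn(sprintf(paste0("bleach correction rises by %.3f in total ",
                        "(max %.3f): k_bleach = %g may be too large"),
                 rise, max(s), k_bleach))
  out <- as_tibble(surv)
  out$survival <- s
  out <- restore_survival(out, surv, k_bleach = k_bleach)
  attr(out, "n_monotonicity_violations") <- n_viol
  out
}

#' @export
print.survival_dist <- function(x, ...) {
  cat(sprintf("<survival_dist: n=%d, dt=%gs, %d time points%s>\n",
              attr(x, "n_total"), attr(x, "dt"), nrow(x),
              if (attr(x, "k_bleach") > 0)
                sprintf(", bleach-corrected (k=%g/s)", attr(x, "k_bleach"))
              else ""))
  NextMethod()
}

#' @param object A `survival_dist`.
#' @param fits Optional list of fitted dwell models to overlay.
#' @param band_level Optional bootstrap confidence band level (e.g. 0.99);
#'   requires the stored durations.
#' @param n_boot Bootstrap replicates for the band.
#' @param ... Unused.
#' @rdname build_survival
#' @method autoplot survival_dist
#' @export
autoplot.survival_dist <- function(object, fits = NULL, band_level = NULL,
                                   n_boot = 200, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (s)", y = "Survival") +
    ggplot2::theme_classic()
  if (!is.null(band_level) && !is.null(attr(object, "durations"))) {
    reps <- replicate(n_boot, {
      b <- resample_survival(object)
      b$survival[match(object$time, b$time)]
    })
    a <- (1 - band_level) / 2
    band <- tibble(time = object$time,
                   lo = apply(reps, 1, quantile, a, na.rm = TRUE),
                   hi = apply(reps, 1, quantile, 1 - a, na.rm = TRUE))
    p <- p + ggplot2::geom_ribbon(
      data = band, ggplot2::aes(x = .data$time, ymin = .data$lo,
                                ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.2)
  }
  p <- p + ggplot2::geom_point(size = 0.8)
  if (!is.null(fits)) {
    for (f in fits) {
      curve <- tibble(time = object$time,
                      survival = predict_survival(f, object$time - object$time[1]))
      p <- p + ggplot2::geom_line(data = curve, colour = "red")
    }
  }
  p
}

# one bootstrap replicate of the survival pipeline (resample durations,
# rebuild, re-truncate, re-correct with the stored settings)
resample_survival <- function(surv) {
  dur <- attr(surv, "durations")
  b <- build_survival(sample(dur, length(dur), replace = TRUE), attr(surv, "dt"))
  if (attr(surv, "min_events") > 0)
    b <- truncate_low_counts(b, attr(surv, "min_events"))
  if (attr(surv, "k_bleach") > 0)
    b <- bleach_correct(b, attr(surv, "k_bleach"))
  b
}
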