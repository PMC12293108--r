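#' Moving-average detrending of an image time series
#'
#' Subtracts, per pixel, the centered moving average over `window` frames
#' (truncated at the ends of the series) and adds back the global mean so
#' the mean intensity — the RICS normalization — is preserved. This removes
#' slow trends (photobleaching, cell movement, immobile structure changes)
#' that would otherwise bias the spatial correlation toward zero lag
#' frequency, i.e. bias fitted diffusion low.
#'
#' @param movie A [movie_stack()].
#' @param window Moving-average window, frames (>= 2).
#' @return A detrended [movie_stack()] of the same dimensions.
#' @export
moving_average_subtract <- function(movie, window = 10) {
  if (window < 2) abort("`window` must be >= 2")
  nf <- dim(movie)[1]
  if (nf < window) abort("`window` exceeds the number of frames")
  m <- matrix(movie, nf, prod(dim(movie)[2:3]))  # frames x pixels
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(1, seq_len(nf) - window %/% 2)
  hi <- pmin(nf, seq_len(nf) + (window - 1) %/% 2)
  ma <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  out <- m - ma + mean(m)
  arr <- array(out, dim = dim(movie))
  movie_stack(arr, pixel_size = attr(movie, "pixel_size"),
              frame_interval = attr(movie, "frame_interval"),
              scan = attr(movie, "scan"))
}

fftshift_idx <- function(n) c((n %/% 2 + 1):n, seq_len(n %/% 2))

#' Spatial autocorrelation surface of a raster-scan series
#'
#' For each frame computes the normalized fluctuation autocorrelation
#' `G(xi, psi) = <dI(x, y) dI(x + xi, y + psi)> / <I>^2`, then averages
#' over frames. The correlation is non-circular (zero-padded FFT with
#' per-lag valid-pair normalization): wrapped pixel pairs would mix
#' unrelated acquisition times and dilute the correlation at large lags.
#' Fluctuations are taken about the series mean. `xi` is the fast
#' (within-line) axis and `psi` the line axis; their lag times are
#' `pixel_dwell * |xi| + line_time * |psi|`.
#'
#' @param movie A detrended [movie_stack()] with scan metadata
#'   (`pixel_dwell`, `line_time`) attached.
#' @return An object of class `acf_surface`: `g` (matrix indexed
#'   psi x xi), `xi`, `psi` (pixel lags, zero-centered), scan metadata,
#'   `pixel_size`, `mean_intensity`.
#' @export
compute_acf <- function(movie) {
  nf <- dim(movie)[1]; ny <- dim(movie)[2]; nx <- dim(movie)[3]
  mean_i <- mean(movie)
  if (!is.finite(mean_i) || mean_i <= 0)
    abort("mean intensity must be positive for ACF normalization")
  # valid-pair counts per lag, same (padded, shifted) layout as the sums
  n_pairs <- outer(ny - abs(seq_len(2 * ny) - (ny + 1)),
                   nx - abs(seq_len(2 * nx) - (nx + 1)))
  acc <- matrix(0, 2 * ny, 2 * nx)
  for (f in seq_len(nf)) {
    # center on the series mean, not the frame's own mean: self-subtraction
    # of the frame mean biases the correlation by ~1/N_particles
    d <- matrix(0, 2 * ny, 2 * nx)
    d[seq_len(ny), seq_len(nx)] <- get_frame(movie, f) - mean_i
    fw <- fft(d)
    acc <- acc + Re(fft(fw * Conj(fw), inverse = TRUE)) / length(d)
  }
  acc <- acc[fftshift_idx(2 * ny), fftshift_idx(2 * nx)]
  g <- (acc / pmax(n_pairs, 1)) / (nf * mean_i^2)
  # keep the central +/- n/2 lag window
  g <- g[ny + 1 - ny %/% 2 + seq_len(ny) - 1, nx + 1 - nx %/% 2 + seq_len(nx) - 1]
  structure(list(g = g,
                 xi = seq_len(nx) - (nx %/% 2 + 1),
                 psi = seq_len(ny) - (ny %/% 2 + 1),
                 scan = attr(movie, "scan"),
                 pixel_size = attr(movie, "pixel_size"),
                 mean_intensity = mean_i, n_frames = nf),
            class = "acf_surface")
}

#' @export
print.acf_surface <- function(x, ...) {
  cat(sprintf("<acf_surface: %dx%d lags, G(0,0)=%.4g, %d frames averaged>\n",
              length(x$psi), length(x$xi),
              x$g[x$psi == 0, x$xi == 0], x$n_frames))
  invisible(x)
}

# one-component free-diffusion RICS model over pixel lags
rics_model <- function(xi, psi, d, g0, offset, w0, wz, pixel_dwell,
                       line_time, pixel_size) {
  tau <- pixel_dwell * abs(xi) + line_time * abs(psi)
  gx <- 1 + 4 * d * tau / w0^2
  gz <- 1 + 4 * d * tau / wz^2
  g0 / (gx * sqrt(gz)) *
    exp(-pixel_size^2 * (xi^2 + psi^2) / (w0^2 * gx)) + offset
}

#' Fit the one-component diffusion model to a RICS surface
#'
#' Least-squares fit of the standard free-diffusion RICS model
#' \deqn{G(\xi,\psi) = \frac{\gamma}{N}
#'   \left(1 + \frac{4D\tau}{w_0^2}\right)^{-1}
#'   \left(1 + \frac{4D\tau}{w_z^2}\right)^{-1/2}
#'   \exp\!\left(
#'     \frac{-\delta r^2 (\xi^2+\psi^2)}{w_0^2 (1 + 4D\tau/w_0^2)}
#'   \right) + \mathrm{offset}}
#' with \eqn{\tau(\xi,\psi) = \tau_p |\xi| + \tau_l |\psi|}, fit over lags
#' within the given radii with the shot-noise-dominated zero lag excluded.
#' The beam waists are calibration inputs, not fit parameters.
#'
#' @param acf An [compute_acf()] result.
#' @param w0,wz Lateral and axial beam waists, um.
#' @param fit_xi,fit_psi Maximum |xi| and |psi| lags included.
#' @param gamma_shape Focal-volume shape factor (3D Gaussian: 0.3536).
#' @return An object of class `rics_fit`: `d` (um^2/s), `n_particles`,
#'   `offset`, `g0`, the fitted data tibble (`xi`, `psi`, `g`, `fitted`,
#'   `resid`), and convergence info.
#' @export
fit_one_component <- function(acf, w0 = 0.25, wz = 1.5,
                              fit_xi = 32, fit_psi = 8,
                              gamma_shape = 0.3536) {
  if (is.null(acf$scan)) abort("scan metadata (pixel_dwell, line_time) missing")
  tp <- acf$scan$pixel_dwell; tl <- acf$scan$line_time
  dr <- acf$pixel_size
  dat <- tidyr::expand_grid(psi = acf$psi, xi = acf$xi)
  dat$g <- as.vector(t(acf$g))  # row-major: psi slow, xi fast -> matches grid
  dat <- dat[abs(dat$xi) <= fit_xi & abs(dat$psi) <= fit_psi &
               !(dat$xi == 0 & dat$psi == 0), ]
  g0_start <- max(dat$g[abs(dat$xi) <= 1 & abs(dat$psi) <= 1])
  if (!is.finite(g0_start) || g0_start <= 0) g0_start <- 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ rics_model(xi, psi, d, g0, offset, w0, wz, tp, tl, dr),
      data = dat,
      start = list(d = 1, g0 = g0_start, offset = 0),
      lower = c(d = 0, g0 = 1e-12, offset = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(failed = TRUE, data = dat), class = "rics_fit"))
  }
  cf <- coef(fit)
  dat$fitted <- stats::predict(fit)
  dat$resid <- dat$g - dat$fitted
  structure(list(d = unname(cf["d"]), g0 = unname(cf["g0"]),
                 offset = unname(cf["offset"]),
                 n_particles = gamma_shape / unname(cf["g0"]),
                 w0 = w0, wz = wz, gamma_shape = gamma_shape,
                 rss = sum(dat$resid^2), data = dat,
                 converged = TRUE, failed = FALSE),
            class = "rics_fit")
}

#' @export
print.rics_fit <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<rics_fit: FAILED>\n"); return(invisible(x))
  }
  cat(sprintf("<rics_fit: D = %.3g um^2/s, N = %.3g, offset = %.2g, RSS = %.3g>\n",
              x$d, x$n_particles, x$offset, x$rss))
  invisible(x)
}

#' @method tidy rics_fit
#' @export
tidy.rics_fit <- function(x, ...) {
  tibble(term = c("d", "n_particles", "offset"),
         estimate = c(x$d, x$n_particles, x$offset))
}

#' @method glance rics_fit
#' @export
glance.rics_fit <- function(x, ...) {
  tibble(d = x$d, n_particles = x$n_particles, offset = x$offset,
         rss = x$rss, n_lags = nrow(x$data))
}

#' @method autoplot rics_fit
#' @export
autoplot.rics_fit <- function(object, ...) {
  prof <- dplyr::filter(object$data, .data$psi %in% c(0, 1) |
                          .data$xi == 0)
  prof$axis <- dplyr::case_when(prof$psi == 0 ~ "fast axis (psi = 0)",
                                prof$xi == 0 ~ "line axis (xi = 0)",
                                TRUE ~ "psi = 1")
  ggplot2::ggplot(prof, ggplot2::aes(x = ifelse(.data$axis ==
                    "line axis (xi = 0)", .data$psi, .data$xi))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g), size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::facet_wrap(~axis, scales = "free") +
    ggplot2::labs(x = "pixel lag", y = "G") +
    ggplot2::theme_classic()
}
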