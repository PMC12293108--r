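#' Dwell-time distribution specification
#'
#' Describes the distribution of true DNA-bound dwell times used by the
#' simulators: a single exponential, a mixture of exponentials (the classic
#' short/nonspecific + long/specific binding model), or a bounded power law
#' (heavy-tailed binding with survival exponent `alpha`).
#'
#' For the power law, `alpha` is the exponent of the *survival* function,
#' \eqn{S(t) = (t/t_{min})^{-\alpha}} truncated at `t_max`; the probability
#' density then decays as \eqn{t^{-(1+\alpha)}}. Smaller `alpha` means
#' heavier tails, i.e. longer-lived binding.
#'
#' @param family One of `"single_exp"`, `"exp_mixture"`, `"power_law"`.
#' @param tau Time constant(s) in seconds (`single_exp`: length 1;
#'   `exp_mixture`: one per component).
#' @param fractions Mixture fractions, summing to 1 (exp_mixture only).
#' @param alpha Survival power-law exponent (> 0, power_law only).
#' @param t_min,t_max Lower and upper cutoffs in seconds (power_law only).
#' @return An object of class `dwell_spec`.
#' @examples
#' dwell_spec("exp_mixture", tau = c(40, 3), fractions = c(0.2, 0.8))
#' dwell_spec("power_law", alpha = 0.7, t_min = 0.5, t_max = 250)
#' @export
dwell_spec <- function(family = c("single_exp", "exp_mixture", "power_law"),
                       tau = NULL, fractions = NULL,
                       alpha = NULL, t_min = NULL, t_max = NULL) {
  family <- match.arg(family)
  if (family == "single_exp") {
    if (is.null(tau) || length(tau) != 1L) abort("single_exp needs one `tau`")
    stop_if_not_positive(tau, "tau")
    fractions <- 1
  } else if (family == "exp_mixture") {
    if (is.null(tau) || is.null(fractions) || length(tau) != length(fractions))
      abort("exp_mixture needs matching `tau` and `fractions`")
    if (any(tau <= 0)) abort("all `tau` must be > 0")
    if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
      abort("`fractions` must be positive and sum to 1")
  } else {
    if (is.null(alpha) || is.null(t_min) || is.null(t_max))
      abort("power_law needs `alpha`, `t_min`, `t_max`")
    stop_if_not_positive(alpha, "alpha")
    stop_if_not_positive(t_min, "t_min")
    if (!(t_min < t_max)) abort("`t_min` must be < `t_max`")
  }
  structure(list(family = family, tau = tau, fractions = fractions,
                 alpha = alpha, t_min = t_min, t_max = t_max),
            class = "dwell_spec")
}

#' Two-state diffusion/binding simulation settings
#'
#' Parameters of the synthetic two-state (freely diffusing vs DNA-bound)
#' emitter model used to emulate nuclear transcription-factor imaging.
#' Molecules perform Brownian motion with state-dependent diffusion
#' coefficient, switch states as a continuous-time two-state process (or draw
#' bound dwell times from a [dwell_spec()]), and disappear by photobleaching.
#'
#' Defaults mirror the mobile/immobile populations seen for nuclear
#' transcription factors: a mobile pool near 3.5 um^2/s and a chromatin-bound
#' pool near 0.003 um^2/s imaged at a 20 ms frame interval with 100 nm pixels.
#'
#' @param d_free,d_bound Diffusion coefficients, um^2/s.
#' @param k_bind,k_unbind Switching rates free->bound and bound->free, 1/s.
#'   `k_unbind` is ignored when `bound_dwell` is given.
#' @param bound_dwell Optional [dwell_spec()] overriding exponential unbinding.
#' @param frame_interval Frame interval, s.
#' @param n_frames Number of frames in the movie.
#' @param n_molecules Number of molecules simulated.
#' @param fov Field of view, um (length 2: x, y).
#' @param pixel_size Pixel size, um.
#' @param bleach_rate Photobleaching rate, 1/s (0 disables bleaching).
#' @param p_bound_start Probability a molecule starts bound. Default is the
#'   stationary probability `k_bind / (k_bind + k_unbind)` (0.5 when both
#'   rates are zero).
#' @return An object of class `two_state_config`.
#' @export
two_state_config <- function(d_free = 3.5, d_bound = 0.003,
                             k_bind = 0.5, k_unbind = 0.5,
                             bound_dwell = NULL,
                             frame_interval = 0.02, n_frames = 6000,
                             n_molecules = 200, fov = c(12.8, 12.8),
                             pixel_size = 0.1, bleach_rate = 2,
                             p_bound_start = NULL) {
  for (nm in c("d_free", "d_bound", "k_bind", "k_unbind", "bleach_rate"))
    stop_if_not_scalar_number(get(nm), nm, lower = 0)
  stop_if_not_positive(frame_interval, "frame_interval")
  stop_if_not_positive(pixel_size, "pixel_size")
  if (n_frames < 2) abort("`n_frames` must be >= 2")
  if (n_molecules < 1) abort("`n_molecules` must be >= 1")
  if (length(fov) != 2L || any(!is.finite(fov)) || any(fov <= 0))
    abort("`fov` must be two positive numbers (um)")
  if (!is.null(bound_dwell) && !inherits(bound_dwell, "dwell_spec"))
    abort("`bound_dwell` must be a dwell_spec")
  if (is.null(p_bound_start)) {
    p_bound_start <- if (k_bind + k_unbind > 0) k_bind / (k_bind + k_unbind) else 0.5
  }
  if (p_bound_start < 0 || p_bound_start > 1)
    abort("`p_bound_start` must be in [0, 1]")
  structure(list(d_free = d_free, d_bound = d_bound, k_bind = k_bind,
                 k_unbind = k_unbind, bound_dwell = bound_dwell,
                 frame_interval = frame_interval, n_frames = n_frames,
                 n_molecules = n_molecules, fov = fov,
                 pixel_size = pixel_size, bleach_rate = bleach_rate,
                 p_bound_start = p_bound_start),
            class = "two_state_config")
}

#' Raster-scan acquisition settings for RICS simulation
#'
#' Describes a confocal raster scan of freely diffusing fluorophores: each
#' pixel samples the Gaussian illumination profile at that pixel's
#' acquisition time (row-major: `time = frame_start + row * line_time +
#' col * pixel_dwell`), which is what gives RICS its sensitivity to
#' diffusion on the pixel and line timescales.
#'
#' Defaults follow a typical single-molecule-grade confocal setting: 12.5 us
#' pixel dwell, 41 nm pixels, 100 frames, a 250 nm lateral / 1.5 um axial
#' beam waist. The default line time is twice the active scan line,
#' reflecting retrace overhead.
#'
#' @param d Diffusion coefficient, um^2/s.
#' @param particle_density Mean particles per um^2 (in the padded
#'   simulation box).
#' @param pixel_dwell Pixel dwell time, s.
#' @param line_time Line period, s; must be >= `frame_size * pixel_dwell`.
#' @param pixel_size Pixel size, um.
#' @param w0,wz Lateral and axial 1/e^2 beam waists, um (`w0 < wz`).
#' @param frame_size Frame edge length, pixels (square frames).
#' @param n_frames Number of frames.
#' @param brightness Photons per particle per pixel dwell at beam center.
#' @return An object of class `raster_config`.
#' @export
raster_config <- function(d = 1, particle_density = 1,
                          pixel_dwell = 12.5e-6, line_time = NULL,
                          pixel_size = 0.041, w0 = 0.25, wz = 1.5,
                          frame_size = 128, n_frames = 100,
                          brightness = 50) {
  stop_if_not_scalar_number(d, "d", lower = 0)
  stop_if_not_scalar_number(particle_density, "particle_density", lower = 0)
  stop_if_not_positive(pixel_dwell, "pixel_dwell")
  stop_if_not_positive(pixel_size, "pixel_size")
  stop_if_not_positive(w0, "w0")
  stop_if_not_positive(wz, "wz")
  if (!(w0 < wz)) abort("`w0` must be < `wz`")
  if (frame_size < 4) abort("`frame_size` must be >= 4")
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  if (is.null(line_time)) line_time <- 2 * frame_size * pixel_dwell
  if (line_time < frame_size * pixel_dwell)
    abort("`line_time` must be >= frame_size * pixel_dwell")
  stop_if_not_scalar_number(brightness, "brightness", lower = 0)
  structure(list(d = d, particle_density = particle_density,
                 pixel_dwell = pixel_dwell, line_time = line_time,
                 pixel_size = pixel_size, w0 = w0, wz = wz,
                 frame_size = as.integer(frame_size),
                 n_frames = as.integer(n_frames), brightness = brightness),
            class = "raster_config")
}
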