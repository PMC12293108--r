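#' Draw dwell times from a dwell specification
#'
#' @param spec A [dwell_spec()].
#' @param n Number of draws.
#' @return Numeric vector of dwell times, s.
#' @export
r_dwell <- function(spec, n) {
  if (!inherits(spec, "dwell_spec")) abort("`spec` must be a dwell_spec")
  switch(spec$family,
    single_exp = rexp(n, rate = 1 / spec$tau),
    exp_mixture = {
      comp <- sample.int(length(spec$tau), n, replace = TRUE,
                         prob = spec$fractions)
      rexp(n, rate = 1 / spec$tau[comp])
    },
    power_law = {
      # bounded Pareto with survival exponent alpha: inverse-CDF sampling
      a <- spec$alpha
      lo <- spec$t_min^(-a); hi <- spec$t_max^(-a)
      u <- runif(n)
      (lo - u * (lo - hi))^(-1 / a)
    })
}

#' Simulate two-state (free/bound) diffusing molecules
#'
#' Each molecule starts uniformly in the field of view, performs Brownian
#' steps with per-frame Gaussian displacements of variance
#' `2 * D_state * frame_interval` per axis, switches between the free and
#' bound states as a continuous-time two-state process (bound dwell times
#' optionally drawn from a [dwell_spec()]), and disappears at an
#' exponentially distributed photobleaching time or at the end of the movie.
#'
#' @param cfg A [two_state_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A list with elements
#'   * `tracks`: a [trajectory_set()] with a `state` column
#'     (`"free"`/`"bound"`, the state at the start of each frame);
#'   * `truth`: a list with `dwells` (tibble: `molecule`, `start_s`,
#'     `duration_s`, `censored` — bound intervals cut by bleaching or movie
#'     end are flagged) and `bleach_s` (per-molecule bleach time, `Inf` if
#'     none).
#' @examples
#' sim <- simulate_two_state_tracks(
#'   two_state_config(n_molecules = 5, n_frames = 100), seed = 1)
#' sim$tracks
#' @export
simulate_two_state_tracks <- function(cfg, seed = NULL) {
  if (!inherits(cfg, "two_state_config")) abort("`cfg` must be a two_state_config")
  set_seed_if_given(seed)
  dt <- cfg$frame_interval
  movie_end <- cfg$n_frames * dt

  locs <- vector("list", cfg$n_molecules)
  dwells <- vector("list", cfg$n_molecules)
  bleach_s <- numeric(cfg$n_molecules)

  for (m in seq_len(cfg$n_molecules)) {
    t_bleach <- if (cfg$bleach_rate > 0) rexp(1, cfg$bleach_rate) else Inf
    bleach_s[m] <- t_bleach
    t_end <- min(t_bleach, movie_end)
    n_obs <- min(cfg$n_frames, ceiling(t_bleach / dt))

    # continuous-time state sequence up to t_end
    state <- if (runif(1) < cfg$p_bound_start) "bound" else "free"
    sw_t <- 0; sw_s <- state
    t <- 0; s <- state
    while (t < t_end) {
      hold <- if (s == "free") {
        if (cfg$k_bind > 0) rexp(1, cfg$k_bind) else Inf
      } else if (!is.null(cfg$bound_dwell)) {
        r_dwell(cfg$bound_dwell, 1)
      } else if (cfg$k_unbind > 0) rexp(1, cfg$k_unbind) else Inf
      t <- t + hold
      if (t < t_end) {
        s <- if (s == "free") "bound" else "free"
        sw_t <- c(sw_t, t); sw_s <- c(sw_s, s)
      }
    }

    # ground-truth bound intervals within [0, t_end)
    iv_start <- sw_t
    iv_end <- c(sw_t[-1], max(t, t_end))
    b <- sw_s == "bound"
    if (any(b)) {
      ends <- pmin(iv_end[b], t_end)
      dwells[[m]] <- tibble(molecule = m, start_s = iv_start[b],
                            duration_s = ends - iv_start[b],
                            censored = iv_end[b] > t_end)
    }

    # per-frame states and Brownian positions
    frame_t <- (seq_len(n_obs) - 1) * dt
    st <- sw_s[findInterval(frame_t, sw_t)]
    d_step <- ifelse(st == "bound", cfg$d_bound, cfg$d_free)
    sd_step <- sqrt(2 * d_step * dt)  # sd of step *leaving* each frame
    x <- cumsum(c(runif(1, 0, cfg$fov[1]), rnorm(n_obs - 1, 0, sd_step[-n_obs])))
    y <- cumsum(c(runif(1, 0, cfg$fov[2]), rnorm(n_obs - 1, 0, sd_step[-n_obs])))
    locs[[m]] <- tibble(track_id = m, frame = seq_len(n_obs) - 1L,
                        x_um = x, y_um = y, state = st)
  }

  tracks <- trajectory_set(dplyr::bind_rows(locs),
                           pixel_size = cfg$pixel_size,
                           frame_interval = dt,
                           regime = if (dt <= 0.1) "fast" else "slow")
  list(tracks = tracks,
       truth = list(dwells = dplyr::bind_rows(dwells), bleach_s = bleach_s))
}

#' Simulate observed dwell durations
#'
#' Draws true bound dwell times from a [dwell_spec()], truncates each by an
#' independent exponential photobleaching time and by the observation window,
#' and discretizes to the frame grid: a dwell of duration t observed at frame
#' interval `dt` is recorded as `ceiling(t / dt)` frames (how a tracker
#' counts frames of presence).
#'
#' @param spec A [dwell_spec()].
#' @param bleach_rate Photobleaching rate, 1/s (0 disables).
#' @param frame_interval Frame interval, s.
#' @param n Number of molecules.
#' @param t_obs_max Observation window, s (e.g. movie length); `Inf` disables.
#' @param seed Optional integer seed.
#' @return A tibble with columns `duration_s` (discretized observed
#'   duration), `n_frames`, `true_dwell_s`, and `truncated_by`
#'   (`"none"`, `"bleach"`, or `"end"`).
#' @export
simulate_dwell_durations <- function(spec, bleach_rate = 0, frame_interval = 0.5,
                                     n = 1000, t_obs_max = Inf, seed = NULL) {
  if (!inherits(spec, "dwell_spec")) abort("`spec` must be a dwell_spec")
  if (n < 1) abort("`n` must be >= 1")
  stop_if_not_positive(frame_interval, "frame_interval")
  stop_if_not_scalar_number(bleach_rate, "bleach_rate", lower = 0)
  set_seed_if_given(seed)
  dwell <- r_dwell(spec, n)
  bleach <- if (bleach_rate > 0) rexp(n, bleach_rate) else rep(Inf, n)
  obs <- pmin(dwell, bleach, t_obs_max)
  frames <- pmax(1L, as.integer(ceiling(obs / frame_interval)))
  truncated_by <- dplyr::case_when(
    bleach <= pmin(dwell, t_obs_max) ~ "bleach",
    t_obs_max < pmin(dwell, bleach) ~ "end",
    TRUE ~ "none")
  tibble(duration_s = frames * frame_interval, n_frames = frames,
         true_dwell_s = dwell, truncated_by = truncated_by)
}
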