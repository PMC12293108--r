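# fixture builders shared across test files

# sparse emitters on a jittered grid (guaranteed separation from each other
# and from the field edge), diffusing slowly; returns ground truth + movie
make_grid_movie <- function(n_side = 4, fov = 12.8, n_frames = 20,
                            d = 0.05, pixel_size = 0.1, frame_interval = 0.02,
                            psf_sigma = 0.13, photons = 3000,
                            background = 0, noise = "none", seed = 1) {
  set.seed(seed)
  pitch <- fov / n_side
  centers <- expand.grid(
    x = pitch * (seq_len(n_side) - 0.5),
    y = pitch * (seq_len(n_side) - 0.5))
  n <- nrow(centers)
  locs <- lapply(seq_len(n), function(i) {
    sd_step <- sqrt(2 * d * frame_interval)
    tibble::tibble(
      track_id = i, frame = seq_len(n_frames) - 1L,
      x_um = centers$x[i] + cumsum(c(runif(1, -0.2, 0.2),
                                     rnorm(n_frames - 1, 0, sd_step))),
      y_um = centers$y[i] + cumsum(c(runif(1, -0.2, 0.2),
                                     rnorm(n_frames - 1, 0, sd_step))))
  })
  ts <- trajectory_set(dplyr::bind_rows(locs), pixel_size = pixel_size,
                       frame_interval = frame_interval, regime = "fast")
  npx <- round(fov / pixel_size)
  movie <- render_movie(ts, psf_sigma = psf_sigma,
                        photons_per_frame = photons,
                        background_mean = background, noise = noise,
                        dims = c(npx, npx), seed = seed + 1)
  list(truth = ts, movie = movie)
}

# static mixture of free and bound molecules with exact composition
make_two_pop_tracks <- function(n_free, n_bound, d_free = 3.5,
                                d_bound = 0.003, n_frames = 6000,
                                frame_interval = 0.02, bleach_rate = 2,
                                seed = 1) {
  base <- function(n, p_bound, seed) {
    simulate_two_state_tracks(
      two_state_config(d_free = d_free, d_bound = d_bound, k_bind = 0,
                       k_unbind = 0, p_bound_start = p_bound,
                       n_frames = n_frames, n_molecules = n,
                       frame_interval = frame_interval,
                       bleach_rate = bleach_rate),
      seed = seed)$tracks
  }
  free <- base(n_free, 0, seed)
  bound <- base(n_bound, 1, seed + 1)
  bound$track_id <- bound$track_id + max(free$track_id)
  trajectory_set(dplyr::bind_rows(tibble::as_tibble(free),
                                  tibble::as_tibble(bound)),
                 pixel_size = attr(free, "pixel_size"),
                 frame_interval = frame_interval, regime = "fast")
}

# fraction of ground-truth consecutive-frame links reproduced by tracking:
# a link is recovered if both endpoints are detected within `tol_um` and
# assigned to the same reconstructed track
link_recovery <- function(truth, ts, tol_um = 0.15) {
  truth_tb <- tibble::as_tibble(truth)
  found_tb <- tibble::as_tibble(ts)
  match_loc <- function(frame, x, y) {
    cand <- found_tb[found_tb$frame == frame, ]
    if (nrow(cand) == 0) return(NA_integer_)
    d2 <- (cand$x_um - x)^2 + (cand$y_um - y)^2
    i <- which.min(d2)
    if (d2[i] <= tol_um^2) cand$track_id[i] else NA_integer_
  }
  n_links <- 0L; n_hit <- 0L
  for (id in unique(truth_tb$track_id)) {
    tr <- truth_tb[truth_tb$track_id == id, ]
    if (nrow(tr) < 2) next
    ids <- mapply(match_loc, tr$frame, tr$x_um, tr$y_um)
    same <- !is.na(ids[-1]) & !is.na(ids[-length(ids)]) &
      ids[-1] == ids[-length(ids)]
    n_links <- n_links + (nrow(tr) - 1L)
    n_hit <- n_hit + sum(same)
  }
  n_hit / n_links
}
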