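test_that("two-state simulation is seed-deterministic and validates input", {
  cfg <- two_state_config(n_molecules = 5, n_frames = 50)
  a <- simulate_two_state_tracks(cfg, seed = 7)
  b <- simulate_two_state_tracks(cfg, seed = 7)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth$dwells, b$truth$dwells)
  expect_error(two_state_config(d_free = -1), "d_free")
  expect_error(two_state_config(frame_interval = 0), "frame_interval")
  expect_error(two_state_config(fov = c(-1, 1)), "fov")
})

test_that("zero diffusion freezes all positions", {
  cfg <- two_state_config(d_free = 0, d_bound = 0, k_bind = 1, k_unbind = 1,
                          n_molecules = 4, n_frames = 40, bleach_rate = 0)
  sim <- simulate_two_state_tracks(cfg, seed = 3)
  spans <- track_summary(sim$tracks)$max_span_um
  expect_equal(spans, rep(0, 4))
})

test_that("free Brownian steps have variance 2 D dt per axis", {
  d <- 3.5; dt <- 0.02
  cfg <- two_state_config(d_free = d, k_bind = 0, k_unbind = 0,
                          p_bound_start = 0, n_molecules = 300,
                          n_frames = 400, frame_interval = dt,
                          bleach_rate = 0)
  sim <- simulate_two_state_tracks(cfg, seed = 11)
  tb <- tibble::as_tibble(sim$tracks)
  dx <- unlist(tapply(tb$x_um, tb$track_id, diff))
  dy <- unlist(tapply(tb$y_um, tb$track_id, diff))
  expect_gt(length(dx), 1e5)
  target <- 2 * d * dt
  se <- target * sqrt(2 / length(dx))  # SE of a chi-square variance estimate
  expect_lt(abs(mean(dx^2) - target), 3 * se)
  expect_lt(abs(mean(dy^2) - target), 3 * se)
})

test_that("absorbing bound state makes dwell equal observed lifetime", {
  cfg <- two_state_config(k_bind = 0, k_unbind = 0, p_bound_start = 1,
                          n_molecules = 20, n_frames = 100, bleach_rate = 1)
  sim <- simulate_two_state_tracks(cfg, seed = 5)
  life <- track_summary(sim$tracks)
  dw <- sim$truth$dwells
  expect_equal(nrow(dw), 20)            # one dwell per molecule
  expect_true(all(dw$censored))         # cut by bleach or movie end
  # dwell duration (continuous) covers the observed frames
  expect_true(all(dw$duration_s >= (life$n_frames - 1) *
                    attr(sim$tracks, "frame_interval") - 1e-9))
})

test_that("bound-state run lengths follow the requested dwell distribution", {
  # exact sampler, n = 1e4: KS against the generative family
  d <- simulate_dwell_durations(dwell_spec("single_exp", tau = 4),
                                bleach_rate = 0, frame_interval = 0.5,
                                n = 1e4, seed = 13)
  ks <- suppressWarnings(ks.test(d$true_dwell_s, "pexp", rate = 1 / 4))
  expect_gt(ks$p.value, 0.01)
  spec <- dwell_spec("power_law", alpha = 0.7, t_min = 0.5, t_max = 100)
  d2 <- simulate_dwell_durations(spec, bleach_rate = 0, frame_interval = 0.5,
                                 n = 1e4, seed = 14)
  p_pareto <- function(q) {
    a <- 0.7; lo <- 0.5^(-a); hi <- 100^(-a)
    (lo - pmin(pmax(q, 0.5), 100)^(-a)) / (lo - hi)
  }
  ks2 <- suppressWarnings(ks.test(d2$true_dwell_s, p_pareto))
  expect_gt(ks2$p.value, 0.01)

  # in-track bound runs, long movie so censoring is negligible
  cfg <- two_state_config(k_bind = 2, k_unbind = 2, n_molecules = 100,
                          n_frames = 500, frame_interval = 0.02,
                          bleach_rate = 0)
  sim <- simulate_two_state_tracks(cfg, seed = 13)
  done <- sim$truth$dwells[!sim$truth$dwells$censored, ]
  expect_gt(nrow(done), 300)
  ks3 <- suppressWarnings(ks.test(done$duration_s, "pexp", rate = 2))
  expect_gt(ks3$p.value, 0.01)
})

test_that("dwell duration sampler matches closed-form expectations", {
  # pure exponential: sample mean ~ tau
  d1 <- simulate_dwell_durations(dwell_spec("single_exp", tau = 10),
                                 bleach_rate = 0, frame_interval = 0.5,
                                 n = 1e4, seed = 2)
  # discretization adds ~dt/2 (+dt/2 from ceil, given dt << tau)
  se <- 10 / sqrt(1e4)
  expect_lt(abs(mean(d1$duration_s) - 10.25), 3 * se)
  expect_true(all(d1$duration_s >= 0.5))
  expect_true(all(abs(d1$duration_s / 0.5 - round(d1$duration_s / 0.5)) < 1e-9))

  # competing exponentials: observed rate is the sum of the rates
  d2 <- simulate_dwell_durations(dwell_spec("single_exp", tau = 10),
                                 bleach_rate = 0.1, frame_interval = 0.5,
                                 n = 1e4, seed = 3)
  expect_lt(abs(mean(d2$duration_s) - 5.25), 3 * 5 / sqrt(1e4))
  expect_gt(mean(d2$truncated_by == "bleach"), 0.4)

  # bounded-Pareto sampler: log-survival slope ~ -alpha over [t_min, t_max/10]
  spec <- dwell_spec("power_law", alpha = 0.7, t_min = 0.5, t_max = 500)
  d3 <- simulate_dwell_durations(spec, bleach_rate = 0, frame_interval = 0.5,
                                 n = 1e4, seed = 4)
  s <- build_survival(d3$duration_s, 0.5)
  u <- s$time - 0.5   # shifted time: survival at k*dt is S_true((k-1)*dt)
  keep <- u >= 0.5 & u <= 50 & s$survival > 0
  slope <- coef(lm(log(s$survival[keep]) ~ log(u[keep])))[2]
  # oracle: the same grid fit applied to the closed-form bounded-Pareto
  # survival (near t_max the log-log curve bends below the asymptote)
  s_true <- (u[keep]^-0.7 - 500^-0.7) / (0.5^-0.7 - 500^-0.7)
  slope_true <- coef(lm(log(s_true) ~ log(u[keep])))[2]
  expect_lt(abs(slope - slope_true), 0.05)
  expect_lt(abs(-slope - 0.7), 0.1)
})

test_that("movie rendering places photons where the molecules are", {
  # zero photons: frames are pure background
  ts <- trajectory_set(data.frame(track_id = 1, frame = 0:1,
                                  x_um = 2, y_um = 2), 0.1, 0.02)
  mv0 <- render_movie(ts, photons_per_frame = 0, background_mean = 5,
                      noise = "none", dims = c(40, 40))
  expect_true(all(mv0 == 5))

  # one immobile emitter, no noise: argmax at the emitter pixel every frame
  ts1 <- trajectory_set(data.frame(track_id = 1, frame = 0:4,
                                   x_um = 2.05, y_um = 1.45), 0.1, 0.02)
  mv1 <- render_movie(ts1, psf_sigma = 0.13, photons_per_frame = 1000,
                      background_mean = 0, noise = "none", dims = c(40, 40))
  for (f in 1:5) {
    am <- which(get_frame(mv1, f) == max(get_frame(mv1, f)), arr.ind = TRUE)
    expect_equal(unname(am[1, ]), c(15, 21))  # row = y px 14, col = x px 20
  }

  # subpixel position: intensity-weighted centroid within 0.05 px of truth
  ts2 <- trajectory_set(data.frame(track_id = 1, frame = 0,
                                   x_um = 2.037, y_um = 1.462), 0.1, 0.02)
  mv2 <- render_movie(ts2, psf_sigma = 0.13, photons_per_frame = 1000,
                      background_mean = 0, noise = "none", dims = c(40, 40))
  img <- get_frame(mv2, 1)
  gx <- matrix(seq_len(40) - 1, 40, 40, byrow = TRUE)
  gy <- matrix(seq_len(40) - 1, 40, 40)
  cx <- sum(img * gx) / sum(img); cy <- sum(img * gy) / sum(img)
  expect_lt(abs(px_to_um(cx, 0.1) - 2.037), 0.005)
  expect_lt(abs(px_to_um(cy, 0.1) - 1.462), 0.005)
  expect_error(render_movie(ts2, psf_sigma = 0), "psf_sigma")
})

test_that("raster-scan simulation freezes when D = 0 and is reproducible", {
  cfg <- raster_config(d = 0, particle_density = 2, frame_size = 32,
                       n_frames = 4, brightness = 100)
  mv <- simulate_raster_scan(cfg, noise = "none", seed = 8)
  f1 <- as.vector(get_frame(mv, 1))
  for (f in 2:4) expect_equal(as.vector(get_frame(mv, f)), f1)
  expect_gt(cor(f1, as.vector(get_frame(mv, 3))), 0.9999)
  mv2 <- simulate_raster_scan(cfg, noise = "none", seed = 8)
  expect_identical(unclass(mv)[], unclass(mv2)[])
  # empty stack at zero density is valid
  cfg0 <- raster_config(d = 1, particle_density = 0, frame_size = 16,
                        n_frames = 2, brightness = 10)
  expect_true(all(simulate_raster_scan(cfg0, noise = "none", seed = 1) == 0))
  expect_error(raster_config(w0 = 2, wz = 1), "w0")
})
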