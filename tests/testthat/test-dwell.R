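test_that("survival construction equals brute-force counting", {
  s <- build_survival(c(1, 1, 2, 4) * 0.5, 0.5)
  expect_equal(s$time, c(0.5, 1, 1.5, 2))
  expect_equal(s$survival, c(1, 0.5, 0.25, 0.25))
  expect_equal(s$events_remaining, c(4L, 2L, 1L, 1L))

  # all durations equal: step function
  s2 <- build_survival(rep(1.5, 7), 0.5)
  expect_equal(s2$survival, c(1, 1, 1))
  expect_equal(nrow(s2), 3)

  # brute-force oracle on random durations
  set.seed(5)
  dur <- sample(1:30, 200, replace = TRUE) * 0.5
  s3 <- build_survival(dur, 0.5)
  for (i in sample(nrow(s3), 10))
    expect_equal(s3$survival[i], mean(dur >= s3$time[i]))

  # DKW-type bound: empirical survival close to the true curve
  d <- simulate_dwell_durations(dwell_spec("single_exp", tau = 10),
                                bleach_rate = 0, frame_interval = 0.1,
                                n = 1e4, seed = 6)
  s4 <- build_survival(d$duration_s, 0.1)
  u <- s4$time - 0.1   # shifted time (discretization convention)
  expect_lt(max(abs(s4$survival - exp(-u / 10))), 0.02)
  expect_error(build_survival(numeric(0), 0.5), "empty")
  expect_error(build_survival(c(0.3), 0.5), "multiples")
})

test_that("low-count truncation follows the threshold rule", {
  dur <- c(rep(0.5, 60), rep(1, 11), rep(1.5, 24), rep(2, 5))
  s <- build_survival(dur, 0.5)   # remaining: 100, 40, 29, 5
  expect_equal(s$events_remaining, c(100L, 40L, 29L, 5L))
  tr <- truncate_low_counts(s, 30)
  expect_equal(nrow(tr), 2)
  # min_events = 0 is the identity
  expect_equal(nrow(truncate_low_counts(s, 0)), 4)
  # everything truncated -> error
  s29 <- build_survival(rep(0.5, 29), 0.5)
  expect_error(truncate_low_counts(s29, 30), "min_events")
})

test_that("bleach correction inverts exponential bleaching exactly", {
  dt <- 0.5
  k <- 0.05; kb <- 0.02
  times <- dt * (1:100)
  u <- times - dt
  obs <- exp(-(k + kb) * u)
  s <- build_survival(rep(dt, 5), dt)  # template for class structure
  s <- s[rep(1, 100), ]
  s$time <- times; s$survival <- obs; s$events_remaining <- rep(1e4L, 100)
  s <- smtkit:::restore_survival(s, build_survival(rep(dt, 5), dt))
  corr <- bleach_correct(s, kb)
  expect_equal(corr$survival, exp(-k * u), tolerance = 1e-12)
  # k_bleach = 0 is the identity
  expect_equal(bleach_correct(s, 0)$survival, s$survival)
  # heavy over-correction warns
  expect_warning(bleach_correct(s, 0.5), "too large")
})

test_that("bleach correction restores a power-law survival end to end", {
  spec <- dwell_spec("power_law", alpha = 0.7, t_min = 0.5, t_max = 1e4)
  d <- simulate_dwell_durations(spec, bleach_rate = 0.02, frame_interval = 0.5,
                                n = 2e4, t_obs_max = 250, seed = 41)
  surv <- bleach_correct(truncate_low_counts(build_survival(d$duration_s, 0.5),
                                             30), 0.02)
  fit <- fit_power_law(surv, n_boot = 0)
  expect_lt(abs(fit$alpha - 0.7), 0.05)

  # sup-norm recovery of the generative survival on the fitted domain
  u <- surv$time - surv$time[1]
  s_true <- (pmax(u, 0.5)^-0.7 - 1e4^-0.7) / (0.5^-0.7 - 1e4^-0.7)
  s_true[u < 0.5] <- 1
  expect_lt(max(abs(surv$survival - s_true)), 0.03)
})

test_that("exponential-mixture fitting matches a grid-search oracle", {
  # degenerate recovery on single-exponential data
  d <- simulate_dwell_durations(dwell_spec("single_exp", tau = 10),
                                bleach_rate = 0, frame_interval = 0.5,
                                n = 5e3, seed = 8)
  surv <- truncate_low_counts(build_survival(d$duration_s, 0.5), 30)
  f2 <- fit_exp_mixture(surv, 2, n_boot = 0)
  degenerate <- max(f2$fractions) > 0.95 ||
    abs(f2$tau[1] / f2$tau[2] - 1) < 0.25
  expect_true(degenerate)

  # small fixture: optimizer SSE beats a dense grid search
  dur <- c(2, 1, 1, 3, 5, 1, 2, 8, 1, 1, 2, 4, 13, 1, 2, 1, 6, 1, 3, 21) * 0.5
  sf <- build_survival(dur, 0.5)
  ff <- fit_exp_mixture(sf, 2, n_boot = 0)
  dom_u <- sf$time - sf$time[1]
  keep <- dom_u > 0 & sf$survival > 0
  sse_of <- function(t1, t2, fl) {
    sh <- fl * exp(-dom_u[keep] / t1) + (1 - fl) * exp(-dom_u[keep] / t2)
    sum((log(sh) - log(sf$survival[keep]))^2)
  }
  grid <- expand.grid(t1 = 10^seq(-1, 2, length.out = 30),
                      t2 = 10^seq(-1, 2, length.out = 30),
                      fl = seq(0.05, 0.95, by = 0.05))
  grid_best <- min(mapply(sse_of, grid$t1, grid$t2, grid$fl))
  expect_lte(ff$sse_log, grid_best + 1e-8)
})

test_that("biexponential parameters are recovered from simulated dwell data", {
  d <- simulate_dwell_durations(
    dwell_spec("exp_mixture", tau = c(40, 3), fractions = c(0.2, 0.8)),
    bleach_rate = 0, frame_interval = 0.5, n = 2e4, t_obs_max = 250,
    seed = 12)
  surv <- truncate_low_counts(build_survival(d$duration_s, 0.5), 30)
  fit <- fit_exp_mixture(surv, 2, n_boot = 50, seed = 1)
  sm <- summarize_dwell(fit)
  expect_lt(abs(sm$tau_long - 40) / 40, 0.15)
  expect_lt(abs(sm$f_long - 0.2), 0.05)
  # bootstrap CI brackets the estimate
  ci <- fit$ci
  expect_true(all(ci$conf.low <= ci$estimate + 1e-9))
  expect_true(all(ci$conf.high >= ci$estimate - 1e-9))
})

test_that("bleach calibration selects by BIC and extracts the smallest rate", {
  # single-exponential control: k_bleach recovered within 5%
  d <- simulate_dwell_durations(dwell_spec("single_exp", tau = 100),
                                bleach_rate = 0, frame_interval = 0.5,
                                n = 2e4, seed = 14)
  cal <- calibrate_bleach(truncate_low_counts(build_survival(d$duration_s, 0.5),
                                              30))
  expect_lt(abs(cal$k_bleach - 0.01) / 0.01, 0.05)

  # tri-exponential control: 3 components selected, smallest rate ~ 0.01/s
  d3 <- simulate_dwell_durations(
    dwell_spec("exp_mixture", tau = c(100, 5, 0.5),
               fractions = c(0.3, 0.4, 0.3)),
    bleach_rate = 0, frame_interval = 0.5, n = 5e4, seed = 15)
  cal3 <- calibrate_bleach(truncate_low_counts(build_survival(d3$duration_s,
                                                              0.5), 30))
  expect_equal(cal3$selected$n_components, 3)
  expect_lt(abs(cal3$k_bleach - 0.01) / 0.01, 0.15)
})

test_that("power-law fitting matches exact curves and the convention", {
  # exact S = (u/u1)^-0.5 on the grid
  dt <- 0.5
  times <- dt * (1:200)
  u <- times - dt
  s_tab <- build_survival(rep(dt, 5), dt)[rep(1, 200), ]
  s_tab$time <- times
  s_tab$survival <- c(1, (u[-1] / dt)^-0.5)
  s_tab$events_remaining <- rep(1000L, 200)
  s_tab <- smtkit:::restore_survival(s_tab, build_survival(rep(dt, 5), dt))
  fit <- fit_power_law(s_tab, n_boot = 0)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-10)
  expect_equal(fit$amplitude, 1, tolerance = 1e-10)
  expect_error(fit_power_law(s_tab[1:3, ], n_boot = 0), "decade")
})

test_that("model selection prefers parsimony and the generative family", {
  # identical residuals: fewer parameters win (BIC penalty)
  d <- simulate_dwell_durations(
    dwell_spec("exp_mixture", tau = c(40, 3), fractions = c(0.2, 0.8)),
    bleach_rate = 0, frame_interval = 0.5, n = 2e4, t_obs_max = 250,
    seed = 18)
  surv <- truncate_low_counts(build_survival(d$duration_s, 0.5), 30)
  f2 <- fit_exp_mixture(surv, 2, n_boot = 0)
  f3 <- fit_exp_mixture(surv, 3, n_boot = 0)
  pl <- fit_power_law(surv, n_boot = 0)
  sel <- select_model(list(exp_2 = f2, exp_3 = f3, power_law = pl))
  expect_equal(sel$best_name, "exp_2")
  expect_equal(unname(sel$table$delta_bic[1]), 0)

  # exponential data: power law loses to the biexponential
  de <- simulate_dwell_durations(dwell_spec("single_exp", tau = 5),
                                 bleach_rate = 0, frame_interval = 0.5,
                                 n = 2e4, seed = 19)
  se <- truncate_low_counts(build_survival(de$duration_s, 0.5), 30)
  fe <- fit_exp_mixture(se, 2, n_boot = 0)
  pe <- fit_power_law(se, n_boot = 0)
  expect_gt(pe$bic, fe$bic)
  expect_gt(pe$bic_curve, fe$bic_curve)

  # power-law data: power law wins
  dp <- simulate_dwell_durations(
    dwell_spec("power_law", alpha = 0.7, t_min = 0.5, t_max = 1e4),
    bleach_rate = 0, frame_interval = 0.5, n = 2e4, t_obs_max = 250,
    seed = 20)
  sp <- truncate_low_counts(build_survival(dp$duration_s, 0.5), 30)
  selp <- select_model(list(exp_2 = fit_exp_mixture(sp, 2, n_boot = 0),
                            power_law = fit_power_law(sp, n_boot = 0)))
  expect_equal(selp$best_name, "power_law")

  # mixed fit domains rejected
  short <- truncate_low_counts(surv, 200)
  f_short <- fit_exp_mixture(short, 2, n_boot = 0)
  expect_error(select_model(list(f2, f_short)), "domain")
})

test_that("dwell summaries sort components and warn on degeneracy", {
  mk_fit <- function(tau, fr) {
    structure(list(tau = tau, fractions = fr, n_components = length(tau),
                   failed = FALSE), class = "exp_mixture_fit")
  }
  sm <- summarize_dwell(mk_fit(c(40, 3), c(0.2, 0.8)))
  expect_equal(sm$tau_long, 40)
  expect_equal(sm$tau_short, 3)
  expect_equal(sm$f_long, 0.2)
  expect_warning(summarize_dwell(mk_fit(c(10, 9.5), c(0.5, 0.5))),
                 "degenerate")
  expect_error(summarize_dwell(mk_fit(c(1, 2, 3), c(0.2, 0.3, 0.5))))
})
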