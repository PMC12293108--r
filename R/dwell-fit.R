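# Fitting operates on shifted time u = t - dt: with ceil(t/dt)
# discretization, the empirical survival at k*dt equals the true survival
# at (k-1)*dt, so models are evaluated at u and the (u = 0, S = 1) point is
# uninformative. The domain shared by all families is u > 0 and S > 0.
fit_domain <- function(surv) {
  dt <- attr(surv, "dt")
  u <- surv$time - surv$time[1]
  keep <- u > 0 & surv$survival > 0
  list(u = u[keep], s = surv$survival[keep], log_s = log(surv$survival[keep]),
       times = surv$time[keep], dt = dt)
}

# BIC from Gaussian-residual SSE on the log-survival curve; m points, p params
bic_from_log_sse <- function(sse_log, m, p) {
  m * log(max(sse_log, 1e-300) / m) + p * log(m)
}

# Duration-level BIC: multinomial likelihood of the observed duration
# histogram under the fitted survival model (bleaching reapplied when the
# curve was corrected). Survival points are strongly dependent (cumulative
# counts), so a curve-level SSE-BIC vastly overstates the evidence for
# extra components; the n independent molecules are the proper sample size.
duration_bic <- function(surv, fit) {
  dur <- attr(surv, "durations")
  if (is.null(dur)) return(NULL)
  dt <- attr(surv, "dt")
  kb <- attr(surv, "k_bleach")
  k_obs <- round(dur / dt)
  k_max <- round(max(fit$fit_times) / dt)   # last fitted frame count
  u <- (seq_len(k_max) - 1) * dt            # shifted times of cell edges
  n_cell <- c(tabulate(k_obs[k_obs < k_max], nbins = k_max - 1),
              sum(k_obs >= k_max))
  log_l_of_s <- function(s_dwell) {
    # observed-duration survival: dwell model with bleaching reapplied
    s <- pmin(s_dwell, 1)
    s[1] <- 1
    s <- s * exp(-kb * u)
    p_cell <- c(-diff(s), s[k_max])  # P(dur = k), k < k_max; P(dur >= k_max)
    sum(n_cell * log(pmax(p_cell, 1e-300)))
  }
  # each family is scored at its own maximum-likelihood optimum (starting
  # from the curve-fit parameters); otherwise BIC punishes the family whose
  # curve fit happens to sit further from its likelihood optimum
  if (inherits(fit, "exp_mixture_fit")) {
    nc <- fit$n_components
    f_min <- fit$min_fraction %||% 0.01
    neg_ll <- function(theta) {
      tau <- exp(theta[seq_len(nc)])
      f <- frac_transform(theta[-seq_len(nc)], nc, f_min)
      -log_l_of_s(mixture_predict(u, tau, f))
    }
    # two starts: curve-fit fractions (clamped off the floor, where the
    # softmax gradient vanishes) and uniform fractions
    theta0 <- list(
      c(log(fit$tau), if (nc > 1)
        frac_inverse(pmax(fit$fractions, 0.05), f_min) else numeric(0)),
      c(log(fit$tau), if (nc > 1)
        frac_inverse(rep(1 / nc, nc), f_min) else numeric(0)))
  } else {
    neg_ll <- function(theta) {
      s <- exp(theta[2]) * (pmax(u, fit$t_start) / fit$t_start)^(-exp(theta[1]))
      -log_l_of_s(s)
    }
    theta0 <- list(c(log(fit$alpha), log(fit$amplitude)))
  }
  opt <- NULL
  for (th0 in theta0) {
    o <- tryCatch(optim(th0, neg_ll, method = "BFGS",
                        control = list(maxit = 400)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(opt) || o$value < opt$value)) opt <- o
  }
  if (is.null(opt)) {
    log_l <- log_l_of_s(pmin(predict_survival(fit, u), 1))
    return(list(bic = -2 * log_l + fit$n_params * log(length(dur)),
                mle = NULL))
  }
  mle <- if (inherits(fit, "exp_mixture_fit")) {
    nc <- fit$n_components
    f_min <- fit$min_fraction %||% 0.01
    tau <- exp(opt$par[seq_len(nc)])
    f <- frac_transform(opt$par[-seq_len(nc)], nc, f_min)
    ord <- order(tau, decreasing = TRUE)
    list(tau = tau[ord], fractions = f[ord])
  } else {
    list(alpha = exp(opt$par[1]), amplitude = exp(opt$par[2]))
  }
  list(bic = 2 * opt$value + fit$n_params * log(length(dur)), mle = mle)
}

mixture_predict <- function(u, tau, fractions) {
  drop(exp(-outer(u, tau, "/")) %*% fractions)
}

# fractions constrained to a floor: a component carrying < min_fraction of
# events is unresolvable from tail noise and would otherwise appear as a
# degenerate huge-tau "floor" component soaking up the deepest points
frac_transform <- function(z, n, f_min) {
  if (n == 1) return(1)
  f_min + (1 - n * f_min) * softmax(z)
}

frac_inverse <- function(f, f_min) {
  n <- length(f)
  p <- (f - f_min) / (1 - n * f_min)
  p <- pmax(p, 1e-6)
  inv_softmax(p / sum(p))
}

# single mixture fit from one start; theta = (log tau_i, logits_{n-1})
mixture_optim <- function(u, target, tau0, f0, fit_scale, maxit = 300,
                          f_min = 0.01) {
  n <- length(tau0)
  theta0 <- c(log(tau0), if (n > 1) frac_inverse(f0, f_min) else numeric(0))
  obj <- function(theta) {
    tau <- exp(theta[seq_len(n)])
    f <- frac_transform(theta[-seq_len(n)], n, f_min)
    s_hat <- mixture_predict(u, tau, f)
    if (fit_scale == "log") sum((log(s_hat) - target)^2)
    else sum((s_hat - target)^2)
  }
  fit <- tryCatch(optim(theta0, obj, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  tau <- exp(fit$par[seq_len(n)])
  f <- frac_transform(fit$par[-seq_len(n)], n, f_min)
  list(tau = tau, fractions = f, value = fit$value,
       converged = fit$convergence == 0)
}

mixture_starts <- function(n_components, u, dt, n_grid = 6) {
  grid <- exp(seq(log(dt), log(max(u) * 2), length.out = n_grid))
  combos <- utils::combn(n_grid, n_components, simplify = FALSE)
  starts <- list()
  for (cb in combos) {
    tau0 <- grid[cb]  # ascending
    if (n_components == 1) {
      starts[[length(starts) + 1]] <- list(tau = tau0, f = 1)
    } else {
      eq <- rep(1 / n_components, n_components)
      starts[[length(starts) + 1]] <- list(tau = tau0, f = eq)
      # a long-lived minority start: 20% on the slowest component
      f2 <- rep(0.8 / (n_components - 1), n_components)
      f2[n_components] <- 0.2
      starts[[length(starts) + 1]] <- list(tau = tau0, f = f2)
    }
  }
  starts
}

#' Fit an exponential-mixture dwell-time model
#'
#' Fits `S(u) = sum_i f_i exp(-u / tau_i)` (fractions summing to 1) to a
#' survival distribution by multi-start bounded nonlinear least squares on
#' the log survival curve (`fit_scale = "linear"` fits on the linear
#' scale). Two BICs are reported over the identical domain for every model
#' family: `bic` (used by [select_model()]) from the duration-level
#' multinomial likelihood with the number of molecules as sample size and
#' each family refined to its likelihood optimum, and `bic_curve` from the
#' Gaussian-residual SSE on the log-survival curve
#' (`m log(SSE/m) + p log(m)`). Survival points are cumulative counts and
#' hence strongly dependent, so the curve-level score overstates the
#' evidence for extra components (see the methods vignette). 95%
#' confidence intervals come from a nonparametric bootstrap over durations
#' that replays truncation and bleach correction.
#'
#' @param surv A `survival_dist` (truncated/corrected as desired).
#' @param n_components Number of exponential components (1-3).
#' @param fit_scale `"log"` (default) or `"linear"` residuals.
#' @param n_boot Bootstrap replicates for CIs (0 skips).
#' @param seed Seed for the bootstrap.
#' @param n_tau_grid Multi-start grid size per component.
#' @param min_fraction Lower bound on mixture fractions; components below
#'   ~1% of events cannot be distinguished from tail noise.
#' @return An object of class `exp_mixture_fit`: `tau` (descending, s),
#'   `fractions`, `bic`, `sse_log`, `m`, `ci` (bootstrap percentile
#'   bounds), `converged`.
#' @export
fit_exp_mixture <- function(surv, n_components = 2,
                            fit_scale = c("log", "linear"),
                            n_boot = 100, seed = 1, n_tau_grid = 6,
                            min_fraction = 0.01) {
  fit_scale <- match.arg(fit_scale)
  if (!n_components %in% 1:3) abort("`n_components` must be 1, 2 or 3")
  dom <- fit_domain(surv)
  if (length(dom$u) < 2 * n_components + 1)
    abort(sprintf("need >= %d time points, have %d",
                  2 * n_components + 1, length(dom$u)))
  target <- if (fit_scale == "log") dom$log_s else dom$s
  best <- NULL
  for (st in mixture_starts(n_components, dom$u, dom$dt, n_tau_grid)) {
    r <- mixture_optim(dom$u, target, st$tau, st$f, fit_scale,
                       f_min = min_fraction)
    if (!is.null(r) && (is.null(best) || r$value < best$value -
                        1e-12 * abs(best$value))) best <- r
  }
  if (is.null(best)) {
    return(structure(list(failed = TRUE, n_components = n_components),
                     class = "exp_mixture_fit"))
  }
  ord <- order(best$tau, decreasing = TRUE)
  tau <- best$tau[ord]; fractions <- best$fractions[ord]
  s_hat <- mixture_predict(dom$u, tau, fractions)
  sse_log <- sum((log(s_hat) - dom$log_s)^2)
  p <- 2 * n_components - 1
  fit <- structure(
    list(tau = tau, fractions = fractions, n_components = n_components,
         bic_curve = bic_from_log_sse(sse_log, length(dom$u), p),
         sse_log = sse_log, m = length(dom$u), n_params = p,
         fit_scale = fit_scale, fit_times = dom$times,
         min_fraction = min_fraction,
         converged = best$converged, failed = FALSE, ci = NULL),
    class = "exp_mixture_fit")
  db <- duration_bic(surv, fit)
  if (is.null(db)) {
    fit$bic <- fit$bic_curve
  } else {
    fit$bic <- db$bic
    fit$mle <- db$mle
  }
  if (n_boot > 0 && !is.null(attr(surv, "durations"))) {
    fit$ci <- boot_mixture_ci(surv, fit, n_boot, seed, fit_scale)
  }
  fit
}

boot_mixture_ci <- function(surv, fit, n_boot, seed, fit_scale) {
  set_seed_if_given(seed)
  n <- fit$n_components
  est <- matrix(NA_real_, n_boot, 2 * n)
  for (b in seq_len(n_boot)) {
    r <- tryCatch({
      bs <- resample_survival(surv)
      dom <- fit_domain(bs)
      target <- if (fit_scale == "log") dom$log_s else dom$s
      mixture_optim(dom$u, target, fit$tau, fit$fractions, fit_scale,
                    maxit = 200, f_min = fit$min_fraction %||% 0.01)
    }, error = function(e) NULL)
    if (!is.null(r)) {
      ord <- order(r$tau, decreasing = TRUE)
      est[b, ] <- c(r$tau[ord], r$fractions[ord])
    }
  }
  terms <- c(paste0("tau_", seq_len(n)), paste0("f_", seq_len(n)))
  tibble(term = terms,
         estimate = c(fit$tau, fit$fractions),
         conf.low = apply(est, 2, quantile, 0.025, na.rm = TRUE),
         conf.high = apply(est, 2, quantile, 0.975, na.rm = TRUE))
}

#' Fit a power-law dwell-time model
#'
#' Fits `S(u) = A (u/u1)^(-alpha)` by least squares on log S versus log u
#' over the truncated domain (`u1` the first fitted time point). `alpha` is
#' the negative log-log slope of the survival function: smaller values mean
#' heavier tails, i.e. longer-lived DNA binding. The 95% CI on `alpha` is a
#' nonparametric bootstrap over durations.
#'
#' @param surv A `survival_dist`.
#' @param t_start Optional lower edge of the fit domain (shifted time), s.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An object of class `power_law_fit`: `alpha`, `amplitude`,
#'   `t_start`, `t_end`, `bic`, `ci_alpha`.
#' @export
fit_power_law <- function(surv, t_start = NULL, n_boot = 1000, seed = 1) {
  dom <- fit_domain(surv)
  if (!is.null(t_start)) {
    keep <- dom$u >= t_start
    dom <- lapply(dom, function(z) if (length(z) > 1) z[keep] else z)
  }
  if (length(dom$u) < 4 || max(dom$u) / min(dom$u) < 10)
    abort("need >= 4 time points spanning >= 1 decade")
  pl <- pl_fit_core(dom$u, dom$log_s)
  sse_log <- pl$sse
  fit <- structure(
    list(alpha = pl$alpha, amplitude = pl$amplitude,
         t_start = min(dom$u), t_end = max(dom$u),
         bic_curve = bic_from_log_sse(sse_log, length(dom$u), 2),
         sse_log = sse_log, m = length(dom$u), n_params = 2,
         fit_times = dom$times, ci_alpha = NULL, failed = FALSE),
    class = "power_law_fit")
  db <- duration_bic(surv, fit)
  if (is.null(db)) {
    fit$bic <- fit$bic_curve
  } else {
    fit$bic <- db$bic
    fit$mle <- db$mle
  }
  if (n_boot > 0 && !is.null(attr(surv, "durations"))) {
    set_seed_if_given(seed)
    alphas <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      alphas[b] <- tryCatch({
        bs <- resample_survival(surv)
        d <- fit_domain(bs)
        if (!is.null(t_start)) {
          k <- d$u >= t_start
          d$u <- d$u[k]; d$log_s <- d$log_s[k]
        }
        pl_fit_core(d$u, d$log_s)$alpha
      }, error = function(e) NA_real_)
    }
    fit$ci_alpha <- unname(quantile(alphas, c(0.025, 0.975), na.rm = TRUE))
  }
  fit
}

pl_fit_core <- function(u, log_s) {
  x <- log(u)
  f <- stats::.lm.fit(cbind(1, x), log_s)
  slope <- f$coefficients[2]
  list(alpha = -slope,
       amplitude = exp(f$coefficients[1] + slope * log(min(u))),
       sse = sum(f$residuals^2))
}

predict_survival <- function(fit, u) UseMethod("predict_survival")

#' @export
predict_survival.exp_mixture_fit <- function(fit, u) {
  mixture_predict(pmax(u, 0), fit$tau, fit$fractions)
}

#' @export
predict_survival.power_law_fit <- function(fit, u) {
  out <- rep(NA_real_, length(u))
  ok <- u > 0
  out[ok] <- fit$amplitude * (u[ok] / fit$t_start)^(-fit$alpha)
  out
}

#' Calibrate the photobleaching rate from a stably bound control
#'
#' Fits 1-, 2- and 3-component exponential mixtures to the survival
#' distribution of a stably DNA-bound control (e.g. HaloTag-histone H2B,
#' whose true residence vastly outlives the fluorophore), selects the best
#' by BIC, and takes the smallest rate (longest time constant, at the
#' selected fit's likelihood optimum) as the bleaching rate of the dye.
#'
#' @param control_surv A `survival_dist` from the control condition
#'   (truncated as for any fit).
#' @param fit_scale Passed to [fit_exp_mixture()].
#' @param source Label for the control (e.g. `"H2B"`).
#' @return An object of class `bleach_calibration`: `k_bleach` (1/s), the
#'   `selected` fit, and a `candidates` table of BICs.
#' @export
calibrate_bleach <- function(control_surv, fit_scale = "log",
                             source = "control") {
  fits <- lapply(1:3, function(k)
    fit_exp_mixture(control_surv, n_components = k, fit_scale = fit_scale,
                    n_boot = 0))
  ok <- !vapply(fits, function(f) isTRUE(f$failed), logical(1))
  if (!any(ok)) abort("both candidate mixture fits failed")
  fits <- fits[ok]
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  sel <- fits[[which.min(bics)]]
  tau_sel <- if (!is.null(sel$mle)) sel$mle$tau else sel$tau
  k_bleach <- 1 / max(tau_sel)
  if (!is.finite(k_bleach) || k_bleach <= 0)
    abort("calibration produced a non-positive bleach rate")
  structure(list(k_bleach = k_bleach, selected = sel, source = source,
                 candidates = tibble(
                   n_components = vapply(fits, `[[`, numeric(1), "n_components"),
                   bic = bics)),
            class = "bleach_calibration")
}

#' @export
print.bleach_calibration <- function(x, ...) {
  cat(sprintf("<bleach_calibration [%s]: k_bleach = %.4g /s (tau = %.3g s), %d-component fit>\n",
              x$source, x$k_bleach, 1 / x$k_bleach,
              x$selected$n_components))
  invisible(x)
}

#' Select the best dwell-time model by BIC
#'
#' Compares fits of different families (exponential mixtures, power law)
#' made on the identical truncated survival distribution and returns the
#' minimum-BIC model with a delta-BIC table. Both the power-law and the
#' two-component summaries are conventionally reported side by side;
#' selection only says which describes the curve more economically.
#'
#' @param fits A (optionally named) list of `exp_mixture_fit` /
#'   `power_law_fit` objects.
#' @return A list of class `model_selection`: `best`, `best_name`, `table`.
#' @export
select_model <- function(fits) {
  if (length(fits) < 2) abort("need >= 2 fits to compare")
  doms <- lapply(fits, `[[`, "fit_times")
  if (!all(vapply(doms[-1], identical, logical(1), doms[[1]])))
    abort("fits were made on different domains; refit on the same survival")
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, model_label, character(1))
  bic <- unname(vapply(fits, `[[`, numeric(1), "bic"))
  p <- unname(vapply(fits, `[[`, numeric(1), "n_params"))
  ord <- order(bic, p)
  tab <- tibble(model = nm, n_params = p, bic = bic,
                delta_bic = bic - min(bic))[ord, ]
  structure(list(best = fits[[ord[1]]], best_name = nm[ord[1]], table = tab),
            class = "model_selection")
}

model_label <- function(f) {
  if (inherits(f, "power_law_fit")) "power_law"
  else sprintf("exp_%d", f$n_components)
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection: best = %s>\n", x$best_name))
  print(x$table)
  invisible(x)
}

#' Long/short dwell-time summary of a two-component fit
#'
#' @param fit A 2-component `exp_mixture_fit`.
#' @return A list: `tau_long`, `tau_short` (s), `f_long` (fraction of
#'   events on the long component). Warns when the two time constants are
#'   within 10% of each other (degenerate split).
#' @export
summarize_dwell <- function(fit) {
  if (!inherits(fit, "exp_mixture_fit") || fit$n_components != 2)
    abort("`fit` must be a 2-component exp_mixture_fit")
  if (fit$tau[1] / fit$tau[2] < 1.1)
    warn("time constants within 10% of each other: long/short split is degenerate")
  list(tau_long = fit$tau[1], tau_short = fit$tau[2],
       f_long = fit$fractions[1])
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<exp_mixture_fit: FAILED>\n"); return(invisible(x))
  }
  cat(sprintf("<exp_mixture_fit: %d components, BIC %.1f>\n",
              x$n_components, x$bic))
  print(tibble(tau_s = x$tau, fraction = x$fractions))
  invisible(x)
}

#' @export
print.power_law_fit <- function(x, ...) {
  ci <- if (is.null(x$ci_alpha)) "" else
    sprintf(" (95%% CI %.3f-%.3f)", x$ci_alpha[1], x$ci_alpha[2])
  cat(sprintf("<power_law_fit: alpha = %.3f%s, BIC %.1f>\n",
              x$alpha, ci, x$bic))
  invisible(x)
}

#' @method tidy exp_mixture_fit
#' @export
tidy.exp_mixture_fit <- function(x, ...) {
  if (!is.null(x$ci)) return(x$ci)
  tibble(term = c(paste0("tau_", seq_along(x$tau)),
                  paste0("f_", seq_along(x$tau))),
         estimate = c(x$tau, x$fractions),
         conf.low = NA_real_, conf.high = NA_real_)
}

#' @method glance exp_mixture_fit
#' @export
glance.exp_mixture_fit <- function(x, ...) {
  tibble(n_components = x$n_components, bic = x$bic,
         bic_curve = x$bic_curve, sse_log = x$sse_log,
         n_points = x$m, converged = x$converged)
}

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  ci <- x$ci_alpha %||% c(NA_real_, NA_real_)
  tibble(term = c("alpha", "amplitude"),
         estimate = c(x$alpha, x$amplitude),
         conf.low = c(ci[1], NA_real_), conf.high = c(ci[2], NA_real_))
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(alpha = x$alpha, bic = x$bic, bic_curve = x$bic_curve,
         sse_log = x$sse_log, n_points = x$m, t_start = x$t_start,
         t_end = x$t_end)
}
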