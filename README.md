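# smtkit

Single-molecule tracking and fluorescence-fluctuation analysis for
quantifying how nuclear proteins — transcription factors in particular —
diffuse and bind DNA in living cells.

Live-cell imaging of sparsely labeled molecules produces two complementary
kinds of evidence about DNA binding. Short exposures (fast SMT, 20 ms)
capture both diffusing and chromatin-bound molecules: per-track
mean-squared-displacement (MSD) fits give a diffusion coefficient for every
molecule, and the distribution of log₁₀ D splits into mobile and immobile
(bound) populations. Long exposures (slow SMT, 500 ms) blur diffusing
molecules into the background, so the lifetime of each remaining immobile
track measures a DNA residence ("dwell") time — once the apparent shortening
caused by fluorophore photobleaching has been calibrated away using a
stably bound control such as histone H2B. Raster image correlation
spectroscopy (RICS) adds an ensemble diffusion coefficient from the spatial
autocorrelation of confocal raster scans.

smtkit implements this entire pipeline as composable, pipe-friendly R
functions:

* **Simulation** (`simulate_two_state_tracks()`, `simulate_dwell_durations()`,
  `render_movie()`, `simulate_raster_scan()`): two-state (free/bound)
  diffusing emitters with photobleaching, camera rendering, and raster
  scans, all with known ground truth and explicit seeds.
* **Tracking** (`detect_particles()`, `link_trajectories()`,
  `filter_fast_tracks()`, `filter_slow_tracks()`, `split_by_mask()`):
  band-pass + Gaussian-fit localization, nearest-neighbor linking with
  distance gates and gap closing, the standard trajectory filters of each
  regime, and region-mask splitting (e.g. nuclear condensates vs
  non-punctate nucleoplasm).
* **Mobility** (`compute_msd()`, `track_diffusion()`, `mobility_summary()`):
  per-track D, the normalized log₁₀ D histogram, mobile/immobile
  classification at the −1.45 threshold (≈0.035 µm²/s), ensemble MSD and
  its AUC.
* **Dwell times** (`build_survival()`, `truncate_low_counts()`,
  `calibrate_bleach()`, `bleach_correct()`, `fit_exp_mixture()`,
  `fit_power_law()`, `select_model()`): survival distributions
  S(t) = Σᵢ fᵢ e^(−t/τᵢ) or S(t) = A (t/t₁)^(−α), photobleach correction
  S_corr(t) = S_obs(t)·e^(k_b t), low-count truncation, BIC model
  comparison, bootstrap confidence intervals.
* **RICS** (`moving_average_subtract()`, `compute_acf()`,
  `fit_one_component()`): 10-frame moving-average detrending, the
  non-circular spatial autocorrelation G(ξ, ψ), and the one-component
  free-diffusion fit with τ(ξ,ψ) = τ_p|ξ| + τ_l|ψ|.

Pipeline drivers `run_fast_smt()`, `run_slow_smt()` and `run_rics()` chain
the stages with provenance logging; results have broom-style `tidy()` /
`glance()` methods and ggplot2 `autoplot()` methods. A thin command-line
wrapper lives at `inst/scripts/smt-pipeline.R`.

## Worked example: residence times with photobleach correction

```r
library(smtkit)

# simulate a slow-SMT experiment: 20,000 bound molecules whose DNA dwell
# times are biexponential (tau 40 s / 3 s, 20% long-lived), observed at
# 500 ms frames under photobleaching (k_b = 0.02/s), 250 s movies
dwells <- simulate_dwell_durations(
  dwell_spec("exp_mixture", tau = c(40, 3), fractions = c(0.2, 0.8)),
  bleach_rate = 0.02, frame_interval = 0.5, n = 2e4, t_obs_max = 250,
  seed = 7)

# an H2B-like bleach control imaged the same way
control <- simulate_dwell_durations(
  dwell_spec("exp_mixture", tau = c(1e4, 10), fractions = c(0.7, 0.3)),
  bleach_rate = 0.02, frame_interval = 0.5, n = 2e4, t_obs_max = 250,
  seed = 8)

cal <- calibrate_bleach(
  truncate_low_counts(build_survival(control$duration_s, 0.5), 30))
cal
#> <bleach_calibration [control]: k_bleach = 0.01998 /s (tau = 50 s), 2-component fit>

surv <- build_survival(dwells$duration_s, 0.5) |>
  truncate_low_counts(30) |>
  bleach_correct(cal$k_bleach)

fits <- list(exp_2 = fit_exp_mixture(surv, 2, n_boot = 100),
             exp_3 = fit_exp_mixture(surv, 3, n_boot = 0),
             power_law = fit_power_law(surv, n_boot = 200))
select_model(fits)
#> <model_selection: best = exp_2>
#> # A tibble: 3 × 4
#>   model     n_params     bic delta_bic
#>   <chr>        <dbl>   <dbl>     <dbl>
#> 1 exp_2            3 134629.       0
#> 2 exp_3            5 134649.      19.8
#> 3 power_law        2 138309.    3680.

tidy(fits$exp_2)
#> # A tibble: 4 × 4
#>   term  estimate conf.low conf.high
#>   <chr>    <dbl>    <dbl>     <dbl>
#> 1 tau_1   41.2     35.3      47.5
#> 2 tau_2    2.96     2.70      3.24
#> 3 f_1      0.198    0.177     0.229
#> 4 f_2      0.802    0.771     0.823
```

Reading the output: the calibration recovers the simulated bleach rate
(0.020/s) from the control's slowest exponential component; after
correction, BIC prefers the two-component exponential over both the
three-component and power-law alternatives (Δ BIC ≥ 19.8), and the fitted
long/short residence times (41.2 s / 2.96 s) and long-lived fraction
(0.198) bracket the simulated truth (40 s / 3 s / 0.2) within their
bootstrap 95% intervals. On power-law-generated binding, the same
`select_model()` call picks the power law instead; both summaries are
always reported.

`autoplot(surv, fits = fits["exp_2"])` draws the log–log survival curve
with the fit overlaid; `autoplot()` methods likewise exist for mobility
summaries, MSD curves and RICS fits.

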