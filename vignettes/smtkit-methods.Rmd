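---
title: "Models and methods behind smtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtkit)
```

smtkit quantifies how nuclear proteins — transcription factors above all —
move and bind DNA in living cells, from two complementary live-imaging
modalities:

* **Single-molecule tracking (SMT)** of sparsely labeled molecules, in two
  regimes. *Fast* SMT (20 ms exposures, thousands of frames) captures both
  diffusing and chromatin-bound molecules and yields per-molecule diffusion
  coefficients. *Slow* SMT (500 ms exposures, hundreds of frames) blurs out
  diffusing molecules so that only bound, near-immobile molecules remain
  visible; the lifetime of each immobile track measures a DNA residence
  (dwell) time.
* **Raster image correlation spectroscopy (RICS)**, which extracts an
  ensemble diffusion coefficient from the spatial autocorrelation of
  raster-scanned confocal images, exploiting the pixel- and line-time
  structure of the scan.

Everything is validated end to end against a synthetic-data generator with
known ground truth; this vignette explains the models, the defaults, the
numerical choices, and what passing tests do and do not establish about real
data.

## The synthetic-data generator

`simulate_two_state_tracks()` emulates nuclear SMT: molecules switch between
a freely diffusing state and a DNA-bound state (a continuous-time two-state
process, or bound dwells drawn from an explicit `dwell_spec()`), take
Brownian steps with per-axis variance $2 D \Delta t$, and disappear at an
exponential photobleaching time. Defaults mirror the two populations seen
for nuclear transcription factors: $D_\text{free} = 3.5$, $D_\text{bound} =
0.003\ \mu m^2/s$, 100 nm pixels, 20 ms frames. `render_movie()` turns
trajectories into camera frames (integrated Gaussian PSF, Poisson background
and shot noise); `simulate_raster_scan()` produces confocal raster scans in
which every pixel samples the Gaussian beam at that pixel's acquisition
time.

What the generator deliberately does *not* emulate: motion blur within an
exposure (slow-SMT analysis concerns near-immobile molecules, where blur is
negligible — the practical consequence of blur, that fast molecules vanish
from slow-SMT movies, is instead produced by the detector failing on large
inter-frame displacements), fluorophore blinking, EMCCD excess noise, 3D
defocus, and nuclear-boundary confinement. Tests that pass on these
simulations therefore establish the correctness of the estimators under the
stated generative model, not robustness to every camera artifact of real
data.

Dwell times can follow a single exponential, an exponential mixture, or a
**bounded power law**: survival $S(t) = (t/t_{min})^{-\alpha}$ truncated at
$t_{max}$, sampled by inverse CDF. Two conventions matter here:

* $\alpha$ is the exponent of the *survival* function (density tail
  $t^{-(1+\alpha)}$), so reported values fall in the 0.5–1.1 range typical
  of transcription-factor residence analyses, and smaller $\alpha$ means
  longer binding.
* When the simulated experiment observes dwells through a 250 s movie, the
  generative upper cutoff is placed far beyond it ($t_{max} = 10^4$ s,
  hours-scale binding as seen for stably incorporated histones). A cutoff at
  the movie length itself would bend the log–log survival curve inside the
  fitted window and is distinguishable from a genuine power law; with the
  cutoff well beyond the observation window the closed-form fit bias is
  ~0.01 in $\alpha$, far below the reported confidence intervals.

Observed durations are discretized as $\lceil t/\Delta t \rceil$ frames —
how a tracker counts frames of presence. This has an exact consequence used
throughout the fitting code: the empirical survival at $k\Delta t$ equals
the *true* survival at $(k-1)\Delta t$, so all models are evaluated on the
shifted time $u = t - \Delta t$ and no discretization bias correction is
needed.

## Detection, linking, filtering

`detect_particles()` band-passes each frame (difference of Gaussians),
takes local maxima within a 7-pixel detection box at a robust 5-sigma
threshold, and refines each candidate by least-squares 2D Gaussian fitting,
rejecting refinements that move more than 1.5 px (those fall back to the
windowed centroid). `link_trajectories()` performs greedy nearest-neighbor
assignment per frame pair under a hard distance gate, with optional gap
closing. At the emitter densities required for single-molecule work the
greedy assignment coincides with full multiple-target tracing; crowded-scene
disambiguation is out of scope.

Defaults encode the standard analysis settings of each regime: fast tracks
are kept when 8–1000 frames long with at most 5 um of travel from their
origin; slow tracks are kept when their apparent $D$ (from the MSD fit
below) is at most $0.1\ \mu m^2/s$, isolating bound molecules. The linking
gates derive from those expectations: 0.8 um/frame (fast; consistent with
$D \approx 10\ \mu m^2/s$ at 20 ms) and 0.45 um/frame (slow; a 3-sigma gate
at $0.1\ \mu m^2/s$ over 500 ms). Gap closing defaults to 0 frames (fast)
and 1 frame (slow): long binders rarely blink at 500 ms exposures, but
single-frame detection dropouts do occur. Tracks too short for a $D$
estimate (under 5 frames) are dropped from the slow regime by default and
logged; this removes the shortest dwells from the survival analysis, which
is why fitted short-time constants should be interpreted from
`min_events = 0` runs with care.

`split_by_mask()` assigns a track to a region (e.g. a nuclear condensate)
when at least half of its localizations fall on mask-true pixels, enabling
the paired inside/outside dwell analyses.

## Fast-SMT mobility quantities

Per track, the time-averaged MSD over all overlapping pairs is fit over its
first 4 lags by unweighted least squares, $MSD(\tau) = 4 D \tau + b$; the
intercept absorbs the localization-error offset, and 4 points balance bias
and variance at the 8-frame minimum track length. Negative fitted $D$
(noise-dominated immobile tracks) is excluded from histograms and
classification, and counted. The per-cell summary comprises the normalized
$\log_{10} D$ histogram (bins of 0.1 over $[-5, 1]$), the mobile fraction
and mobile:immobile ratio at the $-1.45$ threshold ($10^{-1.45} \approx
0.035\ \mu m^2/s$), the ensemble MSD over the first 10 lags at 20 ms, and
its trapezoidal area (AUC). Because "mobile:immobile ratio" is ambiguous
between a count ratio and a fraction ratio, both the fraction and the count
ratio are returned (they are consistent: $r = f/(1-f)$).

## Dwell-time survival analysis

`build_survival()` is the empirical complement-CDF of observed durations on
the frame grid, carrying cumulative event counts; `truncate_low_counts()`
removes points supported by fewer than 30 remaining events (a floor below
which the tail is statistically meaningless), with `min_events = 0` as the
all-points mode for small paired datasets.

**Photobleach correction.** Fluorophore bleaching truncates dwell
observations. With an independent exponential bleach rate $k_b$, the
observed survival factorizes, $S_{obs}(u) = S_{dwell}(u)\,e^{-k_b u}$, so
`bleach_correct()` multiplies by $e^{k_b (t - t_1)}$ and renormalizes. The
rate comes from `calibrate_bleach()` on a stably bound control (histone
H2B): mixtures with 1–3 components are fit, the best is chosen by BIC, and
the smallest rate — the component that can only be bleaching, since H2B
residence vastly outlives the dye — is $k_b$. The synthetic H2B-like
control uses $\tau_{long} = 10^4$ s (effectively permanent incorporation)
with a 10 s transient minority, so its smallest observed rate is
$k_b + 10^{-4} \approx k_b$. Corrected curves that *rise* materially
(over-correction) trigger a warning with diagnostics, never silent
clipping. Whether the single smallest component or the full control curve
should correct the data is ambiguous in general; the single-rate reading is
the default, and dividing by a full fitted control curve can be composed
manually from the same primitives.

**Model families and fitting.** Two families describe survival curves:
exponential mixtures $S(u) = \sum_i f_i e^{-u/\tau_i}$ (bound populations
with distinct off-rates; the two-component version yields the reported
$\tau_{long}$, $\tau_{short}$, $f_{long}$) and the power law $S(u) = A
(u/u_1)^{-\alpha}$ (a broad continuum of binding timescales). Mixtures are
fit by multi-start bounded least squares on the log survival curve (a
$\tau$ grid of 6 log-spaced values per component, two fraction starts;
linear-scale residuals behind `fit_scale = "linear"`), with fractions
constrained to at least 1%: an unconstrained fit will happily place a
vanishing-fraction component at an enormous $\tau$ just to floor the
deepest tail points, which is not a resolvable population at these sample
sizes. The power law is fit by least squares on $\log S$ versus $\log u$.
Confidence intervals come from a nonparametric bootstrap over durations
(default 1000 replicates for $\alpha$) that replays the full
truncation-and-correction chain per replicate; survival points are strongly
dependent, so covariance-based intervals would be anticonservative.

**Model selection.** Families are compared by BIC on the identical
truncated domain. Two scores are computed. `bic_curve` is the Gaussian
surrogate on the log-survival curve, $m \ln(SSE/m) + p \ln m$. It is
reported but *not* used for selection, because survival points are
cumulative counts: hundreds of curve points share a few dozen tail events,
the effective sample size is far smaller than $m$, and the score
systematically overstates the evidence for extra components. Selection
instead uses `bic`, a duration-level multinomial-likelihood BIC: the fitted
curve implies cell probabilities for each observed duration (with bleaching
reapplied), the molecules are independent, and $BIC = -2\log L + p \ln n$
with $n$ the number of molecules. Each family is refined to its own
likelihood optimum first (multi-start, since the fraction floor is a
gradient dead zone) — otherwise BIC would punish whichever family's curve
fit happened to sit further from its likelihood optimum. Under this score
the generative family (2-exp, 3-exp, power law) is recovered in 20/20 seeds
per family at $n = 2 \times 10^4$ in the package's acceptance suite. Both
power-law and biexponential summaries are always reported side by side;
selection only says which describes the data more economically.

Right-censoring: tracks still present at the movie's last frame enter as
observed durations, matching how track lengths are compiled in practice.
Mass piled at the movie end does not distort the survival curve below it,
and the low-count truncation usually removes the affected points.

## RICS

`moving_average_subtract()` removes, per pixel, the centered 10-frame
moving average and adds back the global mean. This deletes slow trends and
immobile structure — which would otherwise concentrate correlation at low
spatial frequency and bias fitted diffusion low — while leaving fast
fluctuations and the mean (the normalization of $G$) intact. A spatially
uniform constant stack passes through exactly; a static structured pattern
is flattened by design.

`compute_acf()` estimates
$G(\xi, \psi) = \langle \delta I(x,y)\, \delta I(x+\xi, y+\psi) \rangle / \langle I \rangle^2$
per frame and averages. Two estimator choices matter and are verified
against a brute-force double-loop oracle:

* the correlation is **non-circular** (zero-padded FFT, per-lag valid-pair
  normalization) — circular wrapping would pair pixels across row and frame
  boundaries whose acquisition times are unrelated, diluting $G$ by the
  factor $(1-|\xi|/n)(1-|\psi|/n)$;
* fluctuations are taken about the **series mean** rather than each frame's
  own mean — subtracting a frame's self-mean biases its own correlation by
  roughly $1/N_{particles}$.

`fit_one_component()` fits the standard free-diffusion RICS model
$$G(\xi,\psi) = \frac{\gamma}{N} \left(1 + \frac{4D\tau}{w_0^2}\right)^{-1}
\left(1 + \frac{4D\tau}{w_z^2}\right)^{-1/2}
\exp\!\left(\frac{-\delta r^2 (\xi^2+\psi^2)}{w_0^2 (1 + 4D\tau/w_0^2)}\right)
+ \text{offset}, \qquad \tau = \tau_p |\xi| + \tau_l |\psi|,$$
by Levenberg–Marquardt over lags within $|\xi| \le 32$, $|\psi| \le 8$
(fast-axis lags carry the spatial information; line-axis lags carry most of
the temporal decay at these timings), excluding the shot-noise zero lag.
The focal-volume shape factor is fixed at $\gamma = 0.3536$ (3D Gaussian);
beam waists ($w_0 = 0.25$, $w_z = 1.5\ \mu m$ by default) are calibration
inputs, not fit parameters. The surface is frame-averaged before a single
fit; per-frame fitting with averaging of $D$ can be composed from the same
functions if desired.

Simulation scale: validation scans use 64-px frames (a subregion) while
keeping the real line period of a 256-px acquisition (12.5 us dwell, 41 nm
pixels, line time 6.4 ms = twice the active line, a realistic retrace duty
cycle), 100 frames, 10 particles/um^2. The line period matters: with a
proportionally shortened line the temporal decay per line is only ~10% of
the spatial term and the one-component fit becomes ill-conditioned near
$D = 1\ \mu m^2/s$.

## Problem sizes and determinism

All stochastic stages accept explicit seeds and are bit-reproducible given
one. The validation suite uses the study-scale sizes throughout: 2,000
tracks for mobility recovery, $2\times10^4$ dwell observations per survival
fit, 20 seeds per family for selection-rate checks, 1000 bootstrap
replicates for $\alpha$ intervals, and 100-frame raster scans. These sizes
were chosen to match the precision the quantities are reported with (e.g.
$\alpha$ intervals of ~±0.05); larger runs sharpen nothing that the
acceptance checks measure.

## Known limitations

* The detector is a standard band-pass + Gaussian-fit localizer; it does
  not claim operator-level equivalence with any specific proprietary
  watershed implementation, only equivalence of the downstream scientific
  quantities on sparse data.
* Greedy linking is not a crowded-scene tracker.
* The slow-regime default of dropping sub-5-frame tracks biases the short
  end of the dwell distribution (documented above).
* The RICS model assumes free 3D diffusion of one species; two-component
  RICS, cross-correlation RICS and number-and-brightness analysis are out
  of scope.
* Bleach correction assumes bleaching competes as an independent
  exponential; laser-duty-cycle-dominated bleaching should be calibrated
  per acquisition setting (the bleach rate is always an explicit input, no
  universal constant is assumed).
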