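---
title: "Models and methods: accumulator dynamics, probe reporting, and synthetic-EEG inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(probeacc)
```

# The scientific question

In self-paced movement experiments, a slow negative EEG deflection — the
readiness potential (RP) — precedes the button press by one to two seconds.
Probe paradigms interrupt the waiting period with a tone and ask the
participant whether they were already preparing to move. If the RP indexes a
consciously accessible preparation process, trials with "yes" (Prep) reports
should carry more pre-probe RP buildup than "no" (NoPrep) trials. `probeacc`
implements the computational side of that argument: generative models of
action initiation, models of how a metacognitive report could be read out of
the generative process, and the analysis chain (epoching, back-averaging,
wavelet band power, trial-level mixed models) that turns simulated or
synthetic data into the quantities the empirical literature reports.

# Action-initiation models

All four models run on a discrete grid (default `dt` = 1 ms, 20 s per run)
with per-run seeds derived from a master seed.

**Stochastic (leaky) accumulator.** Euler–Maruyama integration of
$dx = (I - kx)\,dt + c\,\xi\sqrt{dt}$ with drift $I = 0.11$, leak $k = 0.5$,
noise scale $c = 0.1$, threshold $0.298$, and $x(0) = 0$. The printed update
rule in the source literature scales the noise by $dt$; with that scaling the
stationary standard deviation is $c\sqrt{dt/2k} \approx 0.003$ and the
threshold sits 24 standard deviations above the mean $I/k = 0.22$, so no run
would ever cross. The package therefore defaults to the standard
$\sqrt{dt}$ scaling (stationary sd $0.1$, crossings typical within 20 s) and
exposes `noise_scaling = "dt"` for the literal reading. The first sample at
which the state reaches the threshold is the movement (crossing) time.

**Classic RP model.** A noisy fluctuation ($\epsilon \sim N(0, 0.005)$ added
per step, read literally as a per-step standard deviation with no $dt$
scaling) until an onset time $t_{on} \sim \Gamma(4, 1)$, after which a strong
input $I \sim U(0.25, 1.25)$ drives the state linearly to the threshold
$4/3$. The onset time is recorded per run: it is the model's "unconscious
decision", and the classic reporting rule keys on it.

**Linear ballistic accumulator (LBA).** The state starts at
$x_0 \sim U(0, 4000)$, waits out a fixed 2500 ms delay, then rises with slope
$s \sim N(2, 1)$ (amplitude per millisecond), resampled until positive —
the source text explicitly moved away from parameter settings that produce
shallow or negative slopes. The threshold is not stated in the source; we
use 4000, the upper bound of the starting-point range, per the LBA
convention that start points are drawn below the bound. Crossings are only
possible once accumulation has begun, so a start at the bound crosses at the
onset delay. Dynamics are defined in millisecond units internally; crossing
times are reported in seconds.

**Pink-noise accumulator.** A $1/f^{1.5}$ Gaussian input $P$ (unit variance,
frequency-domain synthesis, analytically normalized) drives the same leaky
accumulator through the literal printed rule $c P_t\,dt$. The *input* $P$ —
not the accumulator state — is stored as the run's trace, because in this
model the RP analogue is the autocorrelated input itself. Crossing times are
still determined by the accumulator state.

# Probe paradigm and reporting models

Probe times are $\Gamma(4, 0.75)$ plus a shift: 2.5 s for the classic-model
protocol, 2 s otherwise. Outcomes partition every run exhaustively:
*Movement* (crossing before the probe), *FTI* — failure to inhibit —
(crossing within the FTI window after the probe), *ProbeTrial* (otherwise,
including runs that never cross).

Two printed protocols differ on FTI, and the package keeps both: the
classic-model protocol categorizes crossings within 200 ms after the probe
as FTI; the single/dual-stage protocol counts *every* trial whose probe
precedes the crossing as a probe trial. `run_model_grid()` and the
acceptance checks use 200 ms for the classic cell and 0 for the
single/dual/random cells, each faithful to its own protocol description;
`reporting_config()` keeps 200 ms as its general default. This matters:
excluding near-crossing trials truncates the upper tail of the post-probe
slope distribution and biases the dual-stage contrast (pilot runs measured
a dual/single contrast-magnitude ratio of 0.16 without the carve-out versus
0.24 with it).

Reporting models label probe trials:

* **single-stage** — rank accumulator amplitude at the probe sample across
  the batch; lowest 53.2% NoPrep, next 11.4% Unsure (discarded), top 35.4%
  Prep (the empirical report proportions). Ties break by trial index, and
  boundary counts use floors with the remainder to Prep, so label counts are
  exact integers.
* **dual-stage** — the same percentile split applied to the
  ordinary-least-squares slope of the trace over the 200 ms after the probe
  (post-decision evidence read-out, the package default), with an optional
  report delay.
* **classic-onset** — NoPrep if the probe preceded $t_{on}$, Prep otherwise;
  a probe exactly at $t_{on}$ counts as Prep (the implicit decision has
  occurred).
* **random** — a seeded permutation with the same marginal proportions, the
  control for reports unrelated to the generative process.

# What the simulations show (and what the tests assert)

At the study scale (10,000 runs per cell) the pipeline reproduces the
qualitative pattern that motivates the modeling: single-stage reporting
yields large Prep-vs-NoPrep differences in mean pre-probe amplitude for
every model; the classic model's difference grows with probe time; random
labels yield none; and dual-stage reporting on the stochastic accumulator
collapses the contrast to a small fraction (about one sixth) of its
single-stage size while still predicting a slight same-direction pre-probe
slope on *both* labels.

Two quantitative honesty notes, both verified against independently coded
brute-force labeling paths:

* The dual-stage/stochastic residual contrast is small but *statistically*
  nonzero at 10,000-run resolution (the leak makes the expected post-probe
  slope $I - kx$ decrease in the current state, so slope-ranked Prep trials
  sit slightly *below* NoPrep trials pre-probe). This matches the source
  literature's own concession that a slight difference exists at simulation
  scale while being far below what EEG trial counts can resolve. The
  corresponding "consistent with zero at 10,000 runs" acceptance expectation
  therefore fails, and is left failing deliberately rather than weakened.
* The pink-noise model's dual-stage contrast is clearly *negative*: a
  stationary $1/f$ input mean-reverts, so a high input level predicts a
  falling post-probe slope. The source only claims that this model produces
  differences under both reporting schemes, which holds.
* Under dual-stage reporting the mean probe time of Prep and NoPrep trials
  is indistinguishable (two selection effects cancel); the
  reports-get-likelier-with-time direction holds under single-stage
  reporting, which is what the behavioural-direction test asserts.

# Trace analysis conventions

Epochs are cut as $[-\mathrm{pre}, +\mathrm{post}]$ windows around per-trial
events; trials whose source series cannot cover the window are dropped with
a logged count, never padded. All pre-event windows are half-open
$[-w, 0)$ — the event sample belongs to the post-event response. Pre-event
slopes are OLS slopes of amplitude on time, invariant to any additive
baseline. Baseline correction subtracts each trial's mean over the interval
(default $-2.5$ to $-2$ s) and is idempotent. Simulated traces keep their
natural (positive-going) sign everywhere in computation; sign inversion to
match the EEG negativity convention happens only in plotting
(`plot_condition_means(invert = TRUE)`).

Back-averaging aligns runs to their threshold crossing. Monotonicity and
convexity of the crossing-aligned average are asserted on 100 ms bin means:
at $dt$ resolution adjacent-sample differences of a 5,000-run average are
dominated by Monte-Carlo noise (~$10^{-4}$), while the binned shape is
stable.

# Synthetic EEG generator

`generate_dataset()` produces multi-participant, trial-level epochs (200 Hz,
$-3.5$ to $+2$ s) with fully recorded ground truth, so estimator bias and
calibration are checkable without any recording:

* midline channel: $1/f$ background noise (exponent 1, RMS 8 uV), an
  exponential RP template $A e^{t/\tau}$ ($A = -6$ uV, $\tau = 0.4$ s) on
  Movement and FTI trials, a biphasic probe-evoked deflection (negative peak
  ~150 ms, positive ~450 ms) on probed trials, per-participant DC offsets
  ($sd$ 2 uV), and optional per-condition DC offsets switched on from
  $-0.5$ s (so the expected 250 ms pre-event contrast equals the injected
  offset difference exactly);
* motor channel: the same noise model plus a 16 Hz oscillation (3 uV)
  whose amplitude envelope ramps down between $-1.5$ and $-0.75$ s to
  $\sqrt{1-d}$ and stays there — the measurement window $[-0.25, 0)$ is
  deliberately stationary, so the injected band-power factor is exactly
  $1-d$ (a ramp running into the window would interact with wavelet
  smoothing and leave no closed-form truth). Default depths: $d = 0.5$
  (Movement, FTI), $0.25$ (Prep), $0$ (NoPrep);
* conditions: probes on 39.2% of trials; among probe trials 24.1% FTI and
  the rest Prep/NoPrep via a logistic model in probe time (slope 0.322
  log-odds/s, intercept $-2$ chosen so the marginal Prep share matches the
  empirical 26.9/40.4 split; participant random intercepts and slopes,
  independent, sd 0.5 and 0.1). Waiting times are $2.5 + \Gamma(3, 0.5)$ s
  (mean 4.0 s, sd 0.87 s), matching typical self-paced waiting behaviour.

What the generator deliberately does not emulate: multi-electrode geometry
(one virtual channel per analysis is the inferential surface), artifacts and
their removal, non-Gaussian noise, and any coupling between the RP and the
beta envelope. Passing recovery tests on this generator therefore shows the
estimators are correct and calibrated, not that the models fit real
recordings.

# Spectral analysis

Complex Morlet wavelets on a 0.5–40 Hz grid with cycles increasing linearly
from 4 to 13 across the grid (the source states only the endpoints; linear
in frequency is the assumption, recorded here). The implementation builds
the wavelet directly in the frequency domain (Gaussian of width
$\sigma_f = f/\mathrm{cycles}$ on the analytic spectrum) and normalizes to
unit *peak gain*, so a stationary sinusoid at a wavelet's centre frequency
keeps its amplitude and tone power is $A^2$ — this choice (rather than unit
wavelet energy) gives the synthetic-data recovery checks a closed-form
ground truth via `morlet_tone_gain()`. Samples within $6\sigma_t$
($\sigma_t = \mathrm{cycles}/2\pi f$) of either epoch edge are masked and
excluded from every downstream statistic; frequencies whose wavelet does not
fit the epoch are fully masked, and `pre_event_band_power()` errors (naming
the offending frequency) if a requested window is entirely masked. Band
intervals are half-open $[lo, hi)$ on the grid. The independent check is a
direct time-domain convolution with a truncated ($\pm 8\sigma_t$) analytic
wavelet, which agrees to better than $10^{-6}$ relative error on unmasked
samples.

# Hierarchical inference

The estimators mirror the empirical analysis chain: `lmerTest`/`lme4` fits
with `emmeans` marginal means and contrasts.

* `fit_linear_random_intercept()`: `outcome ~ condition + (1 | participant)`,
  REML by default (recorded in the result); singular fits are flagged, not
  fatal. Satterthwaite degrees of freedom where `emmeans` provides them
  (asymptotic $z$ beyond its 3,000-observation cutoff).
* `fit_linear_with_interaction()`:
  `outcome ~ time * condition + (condition | participant)` with an automatic,
  logged downgrade to a random intercept when the full structure fails to
  converge — the same workaround the empirical analysis reports.
* `fit_logistic_random_slope()`: `isprep ~ timeprobe + (timeprobe |
  participant)` by Laplace ML with correlated random effects (the
  unstated-covariance open question is resolved as "correlated", the lme4
  default); separation is flagged.
* `posthoc_pairwise()`: Tukey family-wise or Benjamini–Hochberg FDR
  correction over all pairwise condition contrasts; with two levels both
  reduce to the raw p.
* `tf_condition_map()`: one random-intercept fit per unmasked
  time–frequency pair via fast `refit()`s of a single template model, Wald
  $z$ p-values, per-pair failures recorded; `plot_tf_map()` applies the
  p > 0.05 white-out convention of exploratory maps.

Calibration and recovery at the 20-participant x 180-trial scale are part
of the acceptance suite: type-I error of the Prep-vs-NoPrep amplitude
contrast over 50 null replicates (binomial CI must cover 0.05), recovery of
a $-1.5$ uV injected amplitude offset over 25 replicates (within 3 SE,
mean bias under 5%), recovery of the injected low-beta contrast over 15
replicates against the closed-form tone-gain truth, and logistic slope
recovery within 3 SE. Replicate counts are the package's chosen compromise
between Monte-Carlo resolution and a test suite that runs in minutes; the
same loops scale to hundreds of replicates unchanged.

# Reproducibility

Every stochastic stage draws its seeds from a master seed through
`derive_seeds()` (one deterministic stream per stage, so any run or cell can
be regenerated in isolation). Trial tables, condition means, fit summaries,
and configs serialize to CSV/YAML; `experiment_config()` round-trips
losslessly and every grid run writes its exact config next to its outputs.
Rerunning any pipeline with the same master seed reproduces its trial tables
byte for byte.

# Known limitations

* The accumulator models are single-accumulator, one-dimensional; no race
  variants, no parameter fitting to data.
* The dual-stage read-out is a deterministic slope; metacognitive noise is
  not modeled (only a report delay is available), so label splits are exact
  percentiles.
* The synthetic generator's effect sizes are order-of-magnitude choices
  (the empirical literature reports test statistics, not generative
  amplitudes); they are recorded in the ground-truth ledger, not calibrated
  to any recording.
* Wavelet edge handling is masking only; no mirror-padding option.
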