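---
title: "Microsaccades and perceptual filling-in: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsaccades and perceptual filling-in: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixfill)
```

# The problem

When gaze is held still, visual boundaries adapt and fade; adjacent
surfaces can then perceptually merge ("filling-in", the mechanism behind
Troxler fading and the uniformity illusion). Microsaccades — small,
involuntary saccades during fixation — counteract this fading. The
analysis chain in this package quantifies how boundary properties (color
contrast, retinal eccentricity) and fixational eye movements jointly
determine the *filling-in time* (FT): the fixation duration until an
observer reports that the boundary has vanished.

The chain has five stages, each a module of this package:

1. **Synthetic data** — binocular gaze traces with known injected events
   and trial outcomes drawn from a known mixed-model structure.
2. **Microsaccade detection** — a binocular velocity-threshold detector.
3. **Oculometrics** — retinal-slip drift, exclusion rules, filling-in and
   immobilization times.
4. **Rate dynamics** — report-aligned microsaccade rate with a causal
   kernel.
5. **Mixed models** — REML fits with participant-level case bootstrap.

Because raw data from such experiments are rarely shared, the synthetic
generator is first-class, tested code: every downstream stage is
validated against ground truth, and the statistical stage is validated by
*parameter recovery* — re-fitting models to data generated from known
coefficients.

# The generative model

A trial's outcome is

$$\log \mathrm{FT}_{ij} = \mathbf{x}_{ij}^\top \beta +
  \mathbf{z}_{ij}^\top \mathbf{b}_i + \varepsilon_{ij}, \qquad
  \mathbf{b}_i \sim \mathcal N(0, \mathrm{diag}(\tau^2)), \quad
  \varepsilon_{ij} \sim \mathcal N(0, \sigma^2),$$

for trial $j$ of participant $i$, with fixed effects for standardized
color contrast, eccentricity, trial number and blink count, a 0/1
microsaccade-presence indicator, and the interactions of stimulus
properties with the oculomotor covariates
(see `primary_ft_spec()`). The default coefficients
(`default_ft_effects()`) are the published effect-size estimates the
generator is calibrated to; the intercept is interpreted on an FT scale
of `ft_scale` seconds, i.e. $\mathrm{FT} = \texttt{ft\_scale}\,
e^{\log \mathrm{FT}}$, with `ft_scale = 3.9` s calibrated once so the
mean FT is about 7.5 s. All non-intercept coefficients are invariant to
this scale constant. Natural logarithms are used throughout, in both the
generator and the fitters.

Variance components are not printed in the source tables; the package
uses one fixed, a-priori choice everywhere: random-intercept SD 0.2,
random-slope SDs 0.03 (modest between-participant heterogeneity relative
to the fixed-effect scale), residual SD 0.3.

## Exogeneity of the oculomotor covariates

A subtlety worth spelling out: trial duration depends on the covariates
(through the outcome), so drawing "number of blinks" or "any
microsaccade?" from event streams over the *realized* duration would
correlate those covariates with the outcome residual and bias every
recovery analysis. The generator therefore draws the covariates first:

* `ms_presence` is an exogenous per-trial suppression indicator —
  with probability `p_no_ms` (default 0.10, matching the observed share
  of microsaccade-free trials) a trial produces no events at all.
  On the remaining trials, event counts are Poisson at rate
  `ms_rate / (1 - p_no_ms)`, so the *marginal* event rate stays at
  `ms_rate` (default 0.89 Hz). This mixture also reproduces the
  empirical coexistence of a ~0.9 Hz mean rate with ~10 % zero-event
  trials, which a homogeneous Poisson process cannot.
* `num_blinks` is Poisson at the nominal blink rate times a typical 7-s
  duration. Blink intervals are then *placed* within the realized trial;
  in rare short, crowded trials fewer blinks fit than were drawn, and
  the table keeps the drawn (generative) count — the detection pipeline
  measures its own count from the traces anyway.

Event *times* are uniform over the trial with placement suppressed in
the final 600 ms before the report, emulating the well-known pre-report
microsaccade-rate dip; the rate-dynamics stage must recover that dip.

## Outcome truncation

The 2-s floor (the short-trial exclusion bound) is enforced by redraw,
but from a *symmetric* truncation: each trial's residual is drawn from
$\varepsilon \in [a, -a]$, where $a < 0$ is the floor deficit of its
linear predictor. This support respects the floor by construction and
is symmetric about zero, so $E[\log \mathrm{FT} \mid \mathbf{x}]$
equals the linear predictor *exactly*. The naive alternative —
redraw only when the first draw lands under the floor — is equivalent
to sampling from a left-truncated normal; it shifts the conditional
mean of precisely the trials with the smallest predictors and
measurably attenuates the contrast and microsaccade-presence
coefficients in recovery runs. The symmetric scheme's cost is slightly
lighter residual tails on near-floor trials (harmless for fixed-effect
recovery; mildly conservative for variance components). A linear
predictor at or below the floor itself (absent at default settings)
falls back to the one-sided redraw. The 20-s session timeout is
deliberately *not* imposed on the outcome: timeout
censoring removes the upper tail of exactly those trials with large
positive predictors and would systematically attenuate their
coefficients, i.e. distort the generative law the recovery analyses are
meant to invert. The ~1.5 % of synthetic trials beyond 20 s are kept and
flagged `over_timeout`.

## The microsaccade waveform

Injected events follow a raised-cosine velocity profile. For that
profile, displacement $= V_p T / 2$; requiring the main-sequence
relation $V_p = s \cdot A$ (slope $s$, default 60 (deg/s)/deg) therefore
fixes the duration at $T = 2/s \approx 33$ ms, independent of amplitude.
A 10-ms floor applies, binding only for slopes above 200. One
consequence is that all injected events share a duration — acceptable
for a generator whose purpose is testing detection and rate estimation,
and it makes the detector's smoothing attenuation identical across
amplitudes, so detected events reproduce the main sequence with
correlation ≈ 1. Amplitudes are log-normal (median 20 arcmin, log-SD
0.7) truncated to [3 arcmin, 1.5°], consistent with the empirical range
of microsaccade amplitudes. Directions are uniform while gaze is within
0.2° of fixation and biased back toward the fixation point (±30°
Gaussian spread) once it strays — real microsaccades are
error-correcting, and purely uniform directions would let the
event-displacement walk drift past the 1° gaze-displacement exclusion
in a quarter of trials.

## Drift and noise calibration

Ocular drift is a conjugate 2-D random walk (diffusion
`drift_diffusion`, default 0.001 deg²/s) — deliberately not
self-avoiding; it is the simplest process satisfying the slip metric's
assumptions. White positional noise (`noise_sd`, default 0.05
arcmin/sample/eye, independent between eyes) stands in for tracker
noise. These two defaults were fixed by a one-off calibration so that
(a) the retinal-slip statistic falls in the empirically typical
0.5–1 deg/s band (measured ≈ 0.52 deg/s), (b) injected events of
6 arcmin are recovered with ≥ 90 % recall, and (c) the false-alarm rate
on event-free traces stays below 0.05 Hz. White noise is a simplification:
real trackers have temporally correlated noise and drift is partly
persistent; consequences are discussed under *Limitations*.

# Microsaccade detection

Velocity is the slope of a centered least-squares linear fit over a
31-ms sliding window, per eye and axis — unbiased for linear motion and
standard in this detector family. The per-axis noise scale is the
median-based estimator $\sigma = \sqrt{\langle v^2\rangle_{1/2} -
\langle v\rangle_{1/2}^2}$ and the threshold $\eta = \lambda\sigma$
($\lambda = 5$; participants whose noise floor blurs into the event
distribution conventionally get 6). Candidate samples satisfy the
elliptic criterion $(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$ *simultaneously
in both eyes* (intersection, the stricter reading of binocular
detection); runs of ≥ 8 samples form events; events closer than 12 ms
merge (idempotently); events whose binocular direction changes faster
than 15°/ms are discarded as artifacts (direction is undefined below
0.5 deg/s, where angle is meaningless); amplitudes outside
[3 arcmin, 2°] are dropped (below: drift/noise) or classified as large
saccades (above) and returned separately so exclusion logic can use
them. The amplitude convention is the per-axis max–min bounding box of
the binocular mean trajectory — start-to-end displacement would
underestimate curved events.

Two design notes:

* **Onset refinement.** A 31-ms window anticipates the movement: the
  smoothed velocity crosses threshold ~6 ms before the eye actually
  accelerates. Reported onsets/offsets are therefore trimmed to where
  the binocular speed reaches 20 % of the event's peak, which is
  unbiased for the ballistic profile (measured onset error 0 ± 1 ms);
  the trim never shrinks an event below the minimum duration.
* **Large-saccade classification** is by amplitude only. A sustained
  >30 deg/s speed criterion (an online tracker convention) would
  misclassify ordinary microsaccades, whose *peak* velocity exceeds
  30 deg/s at 0.5° amplitude.

Whether the original detector family used an elliptic or scalar-speed
threshold is not documented for this task; the elliptic form is the
cited tradition's standard and is what is implemented (the threshold is
per-axis, so a scalar variant can be emulated by equal axes).

# Oculometrics

**Retinal slip** divides space into 0.01° squares (≈ one cone receptive
field) and counts squares entered by the binocular mean path per 50-ms
segment, excluding segments containing invalid samples or samples
within 10 ms of a microsaccade. Count converts to speed as
$(\mathrm{count} - 1)\cdot 0.01° / 0.05\,\mathrm{s}$ — the $-1$ makes a
stationary eye score exactly 0. The trial value averages over all valid
segments of the whole trial (a sub-window was considered and rejected
for lack of any principled window).

**Exclusions** follow a fixed precedence so every trial gets exactly one
reason: FT < 2 s → median binocular displacement from fixation > 1° →
blink within 300 ms of the report → large saccade within 300 ms. The
order is a reproducibility convention; the underlying rules are
conjunctive in the source analyses.

**Immobilization time** is the report time minus the last event offset,
retained only beyond 300 ms (shorter gaps may reflect motor execution
rather than perception).

**Per-trial microsaccade rate** divides the event count by FT without
subtracting blink-masked time (a simplicity choice, documented; blink
time is ~1 % of trial time at the default rates). Trials with zero
events have no defined log rate and are excluded from the rate model.

# Rate dynamics

The report-aligned rate uses the causal kernel
$\omega(\tau) = \alpha^2 \tau e^{-\alpha\tau}$ ($\alpha = 1/100$ per ms,
1001-ms support, discretely normalized to unit mass), the standard
one-sided window of the firing-rate tradition; causality means the rate
at $t$ depends only on events at or before $t$. With unequal trial
lengths the denominator at each time point counts only trials long
enough to span it, avoiding edge bias from short trials. Baselines are
means over [−5, −3] s before the report (arithmetic mean, the natural
reading of "average rate"); normalization scales each participant's
curve so its baseline matches the grand mean — participants with a zero
baseline are omitted with a warning since no multiplicative scale can
reach a positive target.

# Mixed models and inference

Continuous predictors (contrast, eccentricity, trial number, blink
count, ocular drift, last-event amplitude) are z-scored over retained
trials; microsaccade presence stays 0/1. Contrast and eccentricity enter
as numeric levels (10/20/30 azimuth-degrees; 2/4/6°) before
standardization. Trial number is standardized across retained trials of
the session, not within block. Fits use `lme4` REML with BOBYQA.

The random-effect covariance is fitted as *independent* variance
components (`||`) by default: a 6-dimensional correlated structure at 21
participants is fragile, and the fixed effects — the inferential surface
— are robust to this simplification. `correlated = TRUE` switches to the
full structure. Printed CIs from correlated-slope fits may therefore
differ slightly; this is a known fidelity caveat.

Inference is by participant-level case bootstrap: whole participants are
resampled with replacement (relabeled uniquely, keeping 21 groups),
the model is re-fitted per resample, and percentile CIs are formed at
the Bonferroni-corrected level $\alpha/k$ over the $k$ non-intercept
terms (99.5 % CIs for the 10-term primary model; 98.33 % for 3-term
models; the balanced subsets use uncorrected 95 %). More than 20 %
failed refits aborts with a diagnostic. The desk-scale default is a few
hundred iterations; full analyses use 10,000.

BIC-guided term retention compares each candidate with and without the
term using **ML** refits (REML likelihoods are not comparable across
fixed-effect structures); a term is removed only if removal lowers BIC,
interactions are considered before main effects, and a parent is never
removed while its interaction is retained.

The balanced subset analysis splits retained trials into
microsaccade-without-blink and neither-event subsets, downsamples the
larger subset per participant (never touching the smaller), and fits
random-intercept models of FT on contrast, eccentricity, trial number
and drift. The cortical-magnification sensitivity refit replaces
eccentricity with $d = \ln(E)/0.063 - 36.54$ mm (`cortical_distance()`),
which maps 10° to ≈ 0.

# Problem sizes

Parameter recovery runs 10 replicates per model family at the full
design size: 21 participants × 360 trials for the primary and rate
models, 630 trials for the balanced subsets, 224 trials per participant
for the immobilization model (matching the retained-trial count of that
analysis). Trace-level validation uses reduced designs (a few
participants, a few trials per block) since a full session of 1-kHz
binocular traces is memory-heavy and adds nothing to the statistical
checks; the bundled analysis scripts state their sizes inline.

# What passing tests do and do not show

The synthetic generator emulates the *structure* of such experiments:
Poisson-like event streams with a pre-report dip, main-sequence
ballistic events over random-walk drift, white tracker noise, blink
gaps, and a log-linear mixed outcome. Passing tests show the chain is
internally consistent and statistically unbiased under that structure.
They do not show robustness to what real data add: correlated tracker
noise and drops, drift persistence and curvature, overshooting or
monocular microsaccades, non-Gaussian outcome tails, or perceptual
reports decoupled from the oculomotor record. The detector's recall
bound, in particular, is specific to the calibrated noise level; a
noisier tracker shifts the amplitude floor upward.

# Known limitations

* Single-coefficient waveform duration (no amplitude–duration scaling).
* Blink-masked time is not removed from the rate denominator.
* The generator's drift covariate used by the outcome model is drawn,
  not derived from the trace's diffusion constant, so trace-level drift
  and table-level drift agree only in distribution.
* Monocular events are out of scope by design.
* The symmetric floor redraw makes near-floor residuals mildly
  platykurtic (lighter-tailed); variance-component estimates on heavily
  floored configurations would be slightly conservative, though fixed
  effects are untouched.
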