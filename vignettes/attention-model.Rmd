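---
title: "A probabilistic model of gaze over a talking face: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probabilistic model of gaze over a talking face: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesim)
```

## The model

`gazesim` simulates where an observer looks while watching a talking face.
The image is partitioned into four areas of interest (AOIs, "zones"): the
eyes, the mouth, the rest of the face (RoF), and everything else (Other).
At every normalized time step the model forms a probability distribution
over these four zones — "how attractive each zone currently is" — and draws
the next gaze position from it. Three components contribute a distribution
each, and the fused attraction is their normalized product:

$$P(I^t) \propto P(I^t_{TD} \mid \beta, \gamma)\; P(I^t_{BU} \mid S^t, \theta)\; P(I^t_{mem} \mid X^t)$$

* **Bottom-up** ($\theta$): static center-surround contrast and
  frame-difference motion, each averaged inside every zone and normalized,
  then mixed as $\theta \cdot \text{static} + (1-\theta) \cdot
  \text{dynamic}$. $\theta = 1$ favours permanent contrast (the eyes);
  $\theta = 0$ favours motion (the articulating mouth, or the event zone).
* **Top-down** ($\beta$, $\gamma$): base preferences $(0.45, 0.45, 0.05,
  0.05)$ for (Eyes, Mouth, RoF, Other). In the eyebrow-raise condition the
  eyes mass is replaced, from an onset time $t_a$ onward, by the learned
  mass $(\beta T + 1)\, p_{Eyes}$ — a mass, deliberately allowed to exceed
  1 before renormalization — where $T$ counts completed exposures
  ($T = \text{trial} - 1$, so trial 1 is naive). The onset $t_a = t_{ER} -
  \gamma T$ advances by $\gamma$ steps per exposure, producing anticipation
  of the event; it is floored at the trial start.
* **Selection history**: a belief over recently visited zones, maintained
  as a discrete Bayes filter — each step the belief is diluted by a
  uniform leak $\epsilon$ (transition matrix with diagonal $1 - 3\epsilon$)
  and then multiplied by an observation likelihood that assigns $p_{hit}$
  to the currently fixated zone. The belief is *inverted* into the
  attraction $(1 - b_i)/3$, so recently visited zones repel the gaze
  (inhibition of return at zone granularity). The inversion output sums to
  one identically for four zones.

The combination switches connecting the three components are fixed
(`inference_settings()`): the bottom-up and top-down links are closed
(multiplicative fusion) and the memory link implements the inversion. No
other configuration is defined.

## Time, trials, windows

A trial is a *speech event* (a spoken sentence) followed by a *non-speech
event* — an eyebrow raise (ER) or lip protrusion (LP). Trials of different
real durations are aligned on normalized time: each event is discretized
into 100 steps of 1% of its duration (`trial_timeline()`), so a trial has
200 steps and the event onset is $t_{ER} = 100$. The *anticipatory window*
is the last 50% of the speech event (steps 50–99); the *detection window*
is the whole non-speech event (steps 100–199). The experiment default is
19 test trials and 20 participants per condition; learning is enabled only
in ER (the LP simulation keeps static priors, as the learning mechanism is
defined for the eyebrow-raise event).

Within one step the schedule is: the memory belief (which summarizes
positions up to and including the current one) is inverted and fused with
the current frame's bottom-up distribution and the trial's top-down
distribution; the next position is drawn; the memory then dilutes and
observes that draw. The fused mathematics fixes dilute-before-observe; the
placement of the draw within the step is our scheduling choice. The gaze
starts on the eyes with a uniform memory belief, and the memory resets at
every trial (trials are separated by an attention getter, so cross-trial
carryover of the selection history is not modelled).

## Parameters

| parameter  | meaning                                     | default / explored values            |
|------------|---------------------------------------------|--------------------------------------|
| `beta`     | strength of top-down learning               | grid 0.1, 0.5, 1, 2, 3, 4, 5         |
| `gamma`    | anticipation speed (steps per exposure)     | grid 0.1, 0.5, 1, 1.5, 2             |
| `theta`    | weight of static saliency, in [0, 1]        | grid 0, 0.05, 0.1, 0.25, 0.5, 0.75, 1|
| `epsilon`  | memory leak per step, in (0, 0.25)          | 0.05                                 |
| `p_hit`    | observation probability of the fixated zone | 0.9                                  |

$\epsilon$ and $p_{hit}$ are fixed, not fitted: the leak is only described
qualitatively ("small") in the underlying account, and the observation
model only directionally, so we set one conventional value each and expose
them in `gaze_params()`. With `epsilon = 0.05` an unrefreshed belief decays
to uniform with rate $(1 - 4\epsilon) = 0.8$ per step (half-life about 3
steps), and `p_hit = 0.9` makes one fixation dominate the recency belief —
together they give a visible but quickly fading inhibition of return.
$\gamma$'s unit is normalized steps per exposure: at the grid maximum
$\gamma = 2$, trial 19 anticipates $2 \times 18 = 36$ steps, comfortably
inside the 50-step anticipatory window.

## Analysis

Gaze summaries use the proportion of total looking time (PTLT): dwell time
per face AOI divided by time on the whole face. Samples in the fourth zone
(elsewhere/away) are excluded from the denominator; a window with no
on-face time yields a missing value, never zero. The preference score is
$PTLT_{Eyes} - PTLT_{Mouth}$. Per-trial anticipatory scores are
baseline-corrected against trial 1 with the two-branch rescaling
$(EM_{t_n} - EM_{t_1})/(1 \mp EM_{t_1})$, which maps $[-1,1]$ into
$[-1,1]$; the tie and the doubly degenerate case $EM_{t_1} = EM_{t_n} =
-1$ are defined as 0. A learning curve is summarized by an ordinary
least-squares regression of the group-mean corrected score on trial number
(trials 2–19, missing trials dropped), retaining the fitted *start* and
*end* values.

Two baseline modes exist: per-participant correction before averaging
(`score_series(..., baseline = "participant")`, matching how the
behavioral literature corrects individual infants) and correction of the
group-mean series (`baseline = "group"`). The model-data comparison and
the grid search default to the group baseline: the comparison operates at
the group-curve level, and dividing by individual trial-1 scores amplifies
single-participant noise through small denominators.

## Fitting

`grid_search()` simulates a full experiment at every $(\beta, \gamma,
\theta)$ combination and scores it by the mean squared error between
simulated and observed regression endpoints (2 per condition). Design
choices:

* **Common random numbers**: every grid point reuses the same per-trial
  seed schedule, so MSE differences reflect parameters, not sampling.
* **Runs per grid point**: each point is evaluated as the endpoint average
  of `n_runs = 4` independent 20-participant experiments. One run's group
  endpoint has a Monte-Carlo standard deviation of roughly 0.007–0.014,
  which is *larger* than the typical endpoint difference between adjacent
  grid values (about 0.005–0.01, measured by 30-seed averaging);
  averaging four runs brings the evaluation error below that feature
  scale. The first run uses the protocol's own seed schedule, so a
  `n_runs = 1` self-fit against data generated with the same seed is
  exactly zero at the generating point.
* **Ties** in the argmin break lexicographically (lowest $\beta$, then
  $\gamma$, then $\theta$).
* `fit_diagnostics()` reports sensitivity (max/min MSE), robustness (size
  of the connected region within 10% of the best), and smoothness (mean
  absolute neighbour difference). They are reported, not enforced.

### Identifiability

The endpoint-MSE objective identifies $\gamma$ well but is nearly flat
along two directions, and users should expect this with group sizes around
20:

* $\beta$ saturates: the learned eyes probability $(\beta T + 1) \cdot
  0.45$ renormalized is already $\approx 0.97$ at $\beta = 2$, $T = 18$,
  so late-trial behaviour hardly separates $\beta = 2$ from $\beta = 5$ —
  only early trials do, weakly. Fits on real groups tend to land at the
  grid extremes for the same reason.
* Baseline correction removes most of $\theta$'s effect, which is mainly a
  *level* shift of the preference score; what survives is the denominator
  of the correction and a modest interaction with learning expression.

Consequently a dataset generated at an interior grid point with a
20-participant group is usually *not* recovered to within one grid step in
all three dimensions: the data-side endpoint noise (~0.007 sd) exceeds the
endpoint contrast between rival parameter combinations, and no amount of
fit-side averaging can undo noise in the data themselves. A same-seed
self-fit recovers the generating point exactly, which separates this
statistical limit from implementation error.

## Synthetic stimuli and data

`stimulus_spec()` describes a schematic talking face; the defaults mirror
the experimental materials: 1800 ms mean sentence duration (range
1180–2200 ms; fixed at the mean by default so targets are deterministic),
1880 ms fixed non-speech event, 25 frames/s (92 rendered frames), and a
64×64 px layout with eyes and mouth rectangles inside a face region. The
rendered face is geometric — sclera/pupil blocks for permanent eye
contrast, an oscillating inner mouth during speech, a moving brow band
(ER) or continued mouth modulation (LP) during the event — because only
its saliency structure matters to the model, not photorealism. Contrast
and motion amplitudes default to 0.8 (eye contrast) and 0.4 (mouth/event
modulation): on the 0–1 intensity scale these give the static map a
decisive eyes peak and the motion map a decisive mouth/event peak, like
the real footage, while keeping all zones nonzero.

`make_saliency_streams()` is the analytic fast path: per-zone streams with
the same argmax structure the pixel pipeline produces (verified against
rendered frames in the tests), letting simulations skip per-frame
convolution. `make_behavioral_dataset()` converts simulated trajectories
into the behavioral file format and replaces each sample independently by
an away-look with probability `lapse_rate` (default 0.1), a deliberately
minimal noise model that exercises the missing-data paths.

What the generator does *not* emulate: real infant oculomotor dynamics
(saccade latencies, fixation durations, smooth pursuit), audiovisual
attention capture, drop-out whole trials, calibration error, or any
participant heterogeneity beyond sampling noise. Tests that pass on these
synthetic data therefore validate the computational pipeline, not claims
about real infants.

## Numerical choices

* Probabilities live in linear space; with four zones and the magnitudes
  involved, underflow is impossible. Distributions are renormalized after
  every arithmetic step and validated to sum to 1 within 1e-9.
* The static saliency dialect is intensity-only center-surround: Gaussian
  blurs at three center scales ($\sigma$ = 1, 2, 4 px) against surrounds at
  2× and 4× the center $\sigma$, absolute differences max-normalized per
  scale (with a 1e-9 floor so flat scales stay zero instead of amplifying
  FFT noise) and averaged. Kernels are capped to the image size. The
  underlying account names the classical method but no parameters; this
  dialect is the package's own, documented choice.
* Motion saliency is $|f_t^2 - f_{t-1}^2|$ per pixel — the sign convention
  (absolute value) is ours; the first frame pairs with itself.
* Zone rectangles are 0-based and half-open; a boundary point belongs to
  the lower-indexed zone. Per-zone *means* (not sums) make the bottom-up
  distribution independent of AOI area.
* Millisecond gaze timestamps are binned proportionally into normalized
  steps per event; the exact resampling kernel of the original toolchain
  is unspecified, so proportional binning is used and documented.
* Per-trial seeds derive from the master seed by a modular Horner hash,
  keeping every seed below $2^{31}$ and the schedule stable across
  platforms.

## Problem sizes

The test suite and the reproduction script run full-protocol simulations
(2 conditions × 20 participants × 19 trials × 200 steps) in tens of
milliseconds thanks to a compiled inner loop, a 245-point grid search with
4 runs per point in about 20 s, and the learning-curve contrasts over 50
seeds in a few seconds. These sizes were chosen to match the experimental
design exactly rather than scaled down.

## Limitations

The model has no oculomotor plant and no real-time scale; it predicts
zone occupancy statistics, not fixation sequences. Learning is modelled
by its *result* (a parametric boost of the eyes prior), not by a learning
rule. Only the four-zone decomposition is supported. The memory component
is spatially blind inside a zone. Fitted parameters inherit the
identifiability limits described above and should be read as descriptive
summaries of a group's learning curve, not as sharp estimates.
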