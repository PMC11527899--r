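---
title: "Methods: event-related fNIRS analysis of swallowing across head positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-related fNIRS analysis of swallowing across head positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirswallow)
```

# The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical blood
oxygenation through the scalp at two near-infrared wavelengths. In an
event-related swallowing experiment, a participant swallows small water
boluses at a fixed cadence while holding the head chin-down, chin-neutral or
chin-up, and the question is whether head posture changes the cortical
hemodynamic response (HDR) to swallowing. `nirswallow` implements the full
analysis for such experiments -- swallow-onset detection from laryngeal
accelerometry gated by respiratory apnea, conversion of raw optical
intensity to hemoglobin concentration changes, event-related median-HDR
summaries, and mixed-model inference -- together with a forward generator
that simulates complete sessions with known ground truth, so every stage of
the inverse analysis can be validated against what was injected.

# The protocol and its generator

A default session (`protocol_spec()`) has 4 blocks; within each block the
three head positions appear in seeded random order, and each position is
held for 8 consecutive swallows spaced 38 s apart, giving 32 swallows per
position (96 per session). Blocks are separated by 210 s of rest. Boluses
(5 ml over 3 s at 100 ml/min) begin 3 s before the expected swallow; bolus
cadence and onset spacing are independent parameters because delivery
cadence and swallow cadence need not coincide exactly, and both are
configurable.

The first onset in each position segment falls 15 s after the segment
starts, leaving room for the 10 s pre-onset epoch window; a 30 s tail is
appended after the final block so the last epoch and response decay remain
in-record.

## Hemodynamic response model

The swallowing HDR is characterized in the literature purely by timing
landmarks: a peak 4--6 s after the event and a return to baseline at
20--30 s. We therefore parameterize a single-gamma kernel directly by those
landmarks:

$$ h(t) = (t/p)^{p/b}\, e^{(p-t)/b}, $$

which is zero at the event, has a unit peak exactly at $t = p$ (default
5 s), and decays monotonically; the scale $b$ is solved in closed form so
that $h(r) = 0.05$ at the return time $r$ (default 25 s). Condition
amplitudes default to 0.6 / 0.9 / 1.4 uM (down / neutral / up) -- the order
of magnitude of reported group means in this paradigm, with the chin-up
position strongest. Deoxyhemoglobin carries $-1/3$ of the oxyhemoglobin
event response, the usual inverted and smaller HbR response; the analysis
itself only uses HbR for the Beer-Lambert inversion and CBSI.

## Noise model and what it does not capture

Each hemisphere receives a shared superficial (scalp) component -- cardiac
(1.1 Hz), respiratory (0.25 Hz) and Mayer (0.1 Hz) oscillations with random
phases plus a random-walk drift -- which long channels pick up with a random
coupling in [0.5, 1] and short-separation channels carry almost unchanged.
On top of that: white sensor noise, Laplacian single-sample motion spikes,
and step shifts persisting to the end of the block (mimicking an optode that
settles in a new position). The generator does *not* model optode-scalp
coupling physics, anatomy-specific light transport, non-stationary
breathing, or swallow-to-swallow response variability; passing tests
therefore demonstrate correctness of the inverse chain under the stated
statistical structure, not performance on arbitrary real recordings.

Short-separation channels are included in the default montage even though a
10-pair cap need not physically include them, because the processing chain
contains a short-separation regression stage that must be exercisable; they
can be disabled (`default_montage(short_channels = FALSE)`), in which case
the stage skips with a warning.

## Auxiliary signals

The accelerometer (4 kHz) is an 80 Hz oscillatory carrier whose amplitude is
modulated by a piecewise-linear burst per swallow: a dip beginning 0.6 s
before onset reaching its trough exactly at onset, a steep rise to 5x
baseline over 0.35 s, and decay back within 1 s. The smoothed-rectified
envelope consequently has a local minimum at the true onset followed by a
rise, which is precisely the feature the detector looks for. Respiration
(1 kHz) is a 0.25 Hz sinusoid held constant (with 0.2 s cross-fades outside
the window) from 0.5 s before to 1.0 s after each onset -- the swallow
apnea. Both signals carry small white noise; the respiration noise default
(0.003 of the breathing amplitude) keeps the smoothed derivative inside an
apnea several standard deviations below the detection threshold, which is
what clean plethysmography looks like relative to the breathing excursion.

# Onset detection

The detection chain follows the classical rectify-smooth-differentiate
recipe: the accelerometer signal is rectified and smoothed with a centered
201-tap triangular (Bartlett) window normalized to unit weight sum
(realized as two passes of a 101-point moving average, so the center tap is
$2/(N+1)$), then differentiated by central differences. Swallow onset is
the first point inside a respiratory apnea where this derivative crosses
zero in a positive direction.

Two details are our own, since visual inspection cannot be automated:

* **Apnea criterion.** An apnea is a maximal interval where the magnitude of
  the smoothed respiration derivative stays below 0.1x its record-wide
  median for at least 0.75 s. The median-relative threshold makes the
  criterion invariant to amplitude scaling, and a record with no modulation
  at all is flagged as one full-length apnea with a warning rather than
  silently producing nothing.
* **Crossing persistence and refractory.** The derivative of a
  rectified-noise envelope crosses zero densely, so a crossing only counts
  if the derivative stays positive for 25 consecutive samples (6.25 ms at
  4 kHz); at most one onset is taken per apnea (the earliest), and onsets
  closer than 2 s are deduplicated keeping the earlier -- one swallow per
  apnea.

Detected onsets are labeled with block, position and within-segment ordinal
from the schedule (half-open segments $[start, end)$); onsets in rest
periods are kept but flagged unverified and excluded downstream. On default
synthetic sessions the detector recovers all 96 onsets within 0.2 s (the
residual ~15 ms bias is the smoothing of the asymmetric envelope corner,
well inside the tolerance).

# From intensity to concentration

The processing order is fixed: optical density, band-pass, Beer-Lambert
inversion, short-separation regression, CBSI.

* **Optical density**: $\Delta OD = -\ln(I/\bar I)$ with the channel's
  record mean as reference. The mean reference only determines an additive
  constant, which the epoch baseline normalization removes; for forward
  simulations the true emitted intensity can be supplied for an exact
  inversion.
* **Band-pass**: order-3 Butterworth, 0.01--0.5 Hz, applied
  forward-backward (zero phase). This removes drift/DC and the cardiac and
  respiratory oscillations; a 0.1 Hz tone passes within a few per mil.
  Spectral assertions in the tests trim 200 s (= 2/low) from each edge:
  we measured the two-pass DC transient of this filter and it needs about
  twice the naive $1/f_{low}$ settling time to fall below $10^{-3}$.
  Filtered data passed downstream is not trimmed.
* **Beer-Lambert inversion**: per sample and channel a 2x2 solve of
  $\Delta OD(\lambda) = d \cdot DPF(\lambda)\,[\varepsilon_{HbO}(\lambda)
  \Delta HbO + \varepsilon_{HbR}(\lambda) \Delta HbR]$, with per-channel
  separations (3 cm long, 0.8 cm short), DPF 6.0 at both wavelengths (a
  common adult default; the choice scales concentrations but cancels in all
  relative comparisons), and a built-in extinction table at 790/830 nm from
  the standard hemoglobin compilations. All optical constants are
  configuration on `optics_table()`, and ill-conditioned tables are
  rejected with the condition number.
* **Short-separation regression**: each long channel is regressed on its
  same-hemisphere short channel over the full record (ordinary least
  squares, per chromophore) and replaced by the residual, which is exactly
  orthogonal to the regressor. A sliding-window variant was considered and
  rejected as default: the superficial coupling in the generator (and
  typically in practice) is stationary within a session, and the static
  projection is deterministic and easier to reason about.
* **CBSI**: with $\alpha = sd(HbO)/sd(HbR)$, $HbO^* = (HbO - \alpha
  HbR)/2$ and $HbR^* = -HbO^*/\alpha$. Any common-mode (motion) component
  cancels exactly and the output pair is exactly anti-correlated -- an
  algebraic identity the tests verify to $10^{-10}$.

# Epochs and the median HDR

Epochs run from 10 s before to 20 s after each onset (30 s for
grand-average display). Window conventions: the baseline is the half-open
$[-10, 0)$ s, the statistic window the closed $[5, 20]$ s, and the onset
sample belongs to neither. Baseline normalization subtracts the per-channel
baseline mean, exactly zeroing the baseline window; the removed means are
retained for the baseline-consistency check.

The per-event statistic is the *median* of the normalized trace over
5--20 s, computed per channel and then averaged across each hemisphere's
channels -- "median over time, then mean over channels", which is the
reading consistent with averaging hemisphere channels separately. The
median is robust: perturbing fewer than half the window samples by any
magnitude cannot move it, which is the point of using it over a mean in the
presence of residual artifacts.

Timing groups take ordinals 1--2 (`first`) and 7--8 (`last`) of each
position segment, plus `all`; the summary table is one row per participant
x position x hemisphere x timing. A paired t-test per position compares
first-vs-last participant-level baseline means (no multiplicity correction,
mirroring the simple per-position verification this check descends from);
identical baselines make the test undefined and are reported as a pass with
a note.

# Inference

The response is modeled with a participant random intercept and candidate
fixed effects position (3 levels), timing (first/last), hemisphere, and
their three two-way interactions -- the three-way interaction is excluded,
matching a candidate set of "three variables and three interactions". The
`all` timing rows are descriptive only and never enter the model. Fits are
REML via `lmerTest` with sum-to-zero factor coding; term tests are type III
with Satterthwaite degrees of freedom (recorded in the result).

Backward elimination removes, at each step, the removable term with the
largest p-value above 0.05, where a main effect only becomes removable once
every interaction containing it is gone (marginality), refitting after each
removal until all retained terms are significant or the model is
intercept-only. The procedure is deterministic given the data. Pairwise
position contrasts use estimated marginal means (equal-weight averaging
over the other retained factors) with Tukey adjustment; for a two-level
factor the Tukey family is a single contrast and equals the unadjusted
test.

On balanced data the fixed-effect estimates coincide with ordinary least
squares, which the tests exploit as an independent oracle.

# Cohort-level generator

Group-level questions (does backward elimination retain position? is the
up-vs-down contrast positive and significant?) require many cohorts of
n = 26, for which simulating raw multi-rate signals is pointlessly
expensive: the signal chain is validated separately and deterministically.
The cohort arm (`simulate_hdr_events()`) therefore draws the event-level
median-HDR scalars directly from the same forward model: condition mean =
amplitude x median of the unit kernel over 5--20 s (`hrf_window_median()`,
about 0.48, giving condition means of roughly 0.29 / 0.43 / 0.67 uM), a
participant intercept with SD 0.7 uM, and event-level noise with SD 2.0 uM.
These two SDs were fixed once so that participant-level cell SDs come out
on the order of 1 uM, the scale reported for this paradigm. Under these
conditions the up-vs-down Tukey contrast is recovered (positive, adjusted
p < .05, with position retained) in well over 80% of seeded cohorts, while
a null generator with equal amplitudes retains position at roughly the
nominal 5--10% rate.

# Problem sizes and determinism

Every generator accepts a seed and is bit-reproducible given one;
`run_pipeline()` derives all stage randomness from a single seed. The test
suite validates signal-level properties on short sessions (1 block, 2--6
swallows per segment) and protocol-level counts plus detector sensitivity
on one full default session; selection/power properties use 50 cohorts of
n = 26 at the event level. These sizes were chosen so the whole suite runs
in about two minutes while every assertion still has the statistical
resolution it needs.

# Known limitations

* The HDR kernel is a fixed deterministic shape; no swallow-to-swallow or
  participant-level latency/shape variability is modeled.
* The apnea and onset detectors are defined for clean plethysmography and
  accelerometry; real recordings with movement unrelated to swallowing
  (coughs, head turns) would need the human verification step the `verified`
  flag models.
* Printed group-level contrast tables in this literature are not numeric
  reproduction targets here: the underlying participant data are not
  public, so the package validates structure (direction and selection
  behavior), not those exact numbers.
* The short-separation stage assumes at least one short channel per
  hemisphere; with none, superficial physiology is only attenuated by the
  band-pass and CBSI.
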