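---
title: "Scoring altered muscle activation patterns in gait: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring altered muscle activation patterns in gait: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amapgait)
```

This vignette records the modeling assumptions, parameter choices and
numerical decisions behind the package, in the spirit of a methods
appendix. The README shows the user-facing workflow; here we explain *why*
the pieces are the way they are.

## The measurement model

The quantity of interest is how far a walker's per-muscle EMG deviates
from healthy activity *within biomechanically equivalent sub-phases* of
the gait cycle. The core assumption is that the biomechanical consequence
of muscle activity is determined by the mechanical state of the leg —
double support, single support, swing — rather than by the percentage of
the time-normalized cycle at which it occurs. Hemiparetic gait shifts
phase boundaries substantially (a paretic swing may start at 75% of the
cycle rather than ~60%), so all comparisons in this package are anchored
to event-defined regions:

1. **DS1** ipsilateral heel strike → contralateral toe off;
2. **SS1/SS2** single support, split at its temporal midpoint;
3. **DS2** contralateral heel strike → ipsilateral toe off;
4. **SW1/SW2** swing, split at its temporal midpoint.

"Halves" of single support and swing are *time* halves. Event-defined
alternatives (e.g. mid-swing by foot clearance) would need kinematics,
which the input data (EMG + forces) does not contain; the temporal
midpoint is the only definition computable from GRF events alone, and it
degrades gracefully under asymmetry because each half rescales with its
parent phase.

Within each region, two components are computed per muscle and stride:
the fraction of the region during which the muscle is on (*timing*, % of
region duration) and the share of the stride's integrated on-envelope
falling in the region (*amplitude*, % of the stride total, so the six
amplitude values sum to 100 whenever the muscle is on at all). Components
are computed per stride and then averaged — the stride count is reported —
rather than pooling samples across strides, so a single corrupted stride
cannot silently dominate and the stride-to-stride spread remains
inspectable.

Deviation is a z-score against the cell-wise mean and SD of a healthy
cohort. The z-scale is the point of the method: healthy activity is very
variable in some cells (e.g. hamstrings in loading) and nearly invariant
in others (plantarflexors off in early swing), and a raw difference in
percentage points would penalize both equally. Scores within ±2.57 — the
99% central window of the standard normal — count as normal. The window
half-width is a parameter (`window`), not a branch: the companion 96%
window, 2.05, is obtained by passing a different value, and
`normal_window_halfwidth()` exposes the analytic mapping. (Printed
critical-value conventions truncate 2.5758 to 2.57; the package keeps the
analytic value and treats 2.57 as the conventional default.)

## On/off detection

Every sample of the linear envelope is dichotomized by k-means with
k = 5 over the *whole trial*, per muscle; the cluster with the lowest mean
amplitude is off, all others on. Five clusters let burst plateaus of
different heights, transition samples and the baseline occupy separate
clusters, so a raised post-stroke baseline still lands in the lowest
cluster while short or spike-like bursts are captured as on.

Numerically, 1-D k-means admits an exact solution: optimal clusters are
contiguous in sorted order, so the globally optimal partition is found by
dynamic programming over unique values with counts as weights
(divide-and-conquer on the argmin, `src/kmeans1d.cpp`). This removes the
initialization/seed sensitivity of Lloyd-type iteration entirely —
identical input gives an identical mask, and pipeline reruns are
bit-reproducible. A deterministic quantile-initialized Lloyd fallback is
included for cross-checking only. Ties between equal-cost splits keep the
lowest split index; since cluster means are strictly increasing over
distinct values, the off cluster is always index 1. The resulting mask
equals thresholding at the midpoint between the off cluster's largest
value and the next cluster's smallest — this boundary is exposed
(`off_boundary`) because it is a useful diagnostic of what "off" meant for
a given trial. No minimum burst duration or gap filling is applied by
default; the dichotomization is taken as-is.

Clustering per trial (not per stride) follows the plain reading of
"each point of the envelope of each muscle": the amplitude distribution
over the whole trial is what anchors the off cluster.

## Preprocessing

The envelope chain is: 4th-order Butterworth high-pass at 20 Hz, run
forward and backward (zero phase); demean; full-wave rectify; 4th-order
Butterworth low-pass at 25 Hz, forward-backward; clip residual negative
ringing to zero. The demean step after the high-pass is redundant in
exact arithmetic but kept, matching the stated processing order.
Zero-phase filtering is realized with odd-reflection padding of three
filter lengths at each end *plus* steady-state initial conditions (the
filter memory preloaded as if the edge sample had been applied forever);
padding alone leaves a visible transient for a 20 Hz cutoff at a 2 kHz
rate because the impulse response far outlasts the pad.

Amplitude is normalized per muscle to the mean over strides of the
within-stride envelope maximum. "Stride" here means the gait cycle of the
analyzed leg — the unit every other computation uses. This walking-based
normalization is used instead of maximum voluntary contraction, which is
unreliable in populations with impaired voluntary drive; individual
strides may exceed 1 after scaling, by construction. A flat channel
(divisor below `1e-12`) raises a degenerate-channel error naming the
channel.

All internal time is seconds; sample `i` owns the half-open interval
`[(i-1)/rate, i/rate)`, so a sample belongs to exactly one region and
mixed-rate EMG/GRF need no resampling. Region membership is by sample
counting, which makes timing values exactly within [0, 100] and amplitude
conservation exact, at the cost of a sub-sample quantization that
vanishes at practical rates (tested: 500 vs 1000 Hz components agree
within 1 percentage point).

## Gait events and propulsion

Heel strike and toe off are threshold crossings of the vertical GRF
(default 20 N, a common force-plate convention; configurable), with
contact and gap episodes shorter than 50 ms removed as noise, crossing
times linearly interpolated between samples, and partial contacts at the
trace edges dropped, so events alternate HS, TO, HS, … Strides whose
contralateral events are missing or out of order are skipped with a
warning rather than failing the trial.

Paretic propulsion is the paretic share (in %) of the bilateral
propulsive impulse, each impulse the trapezoidal integral of the positive
part of the anterior GRF. Each belt is trusted as one leg's force; belt
crosstalk and stepping over the midline are out of scope.

## Normative profiles and scoring conventions

Cohort SDs use the n−1 denominator. Both legs of a healthy subject enter
as separate observations — this doubles the effective sample but treats
within-subject legs as independent, an acknowledged approximation. Speed
bands follow the functional-ambulation strata (< 0.4 m/s → 0.3 m/s norm;
0.4–0.8 → 0.6; > 0.8 → 0.9), with both boundary speeds assigned to the
middle band, as the strict outer inequalities imply.

Healthy self-assessment uses the *leave-in* profile (the scored
observation contributes to the norm); consequently no leave-in |z| can
exceed (n−1)/√n, a property the tests assert. Leave-one-out scoring is
available by rebuilding the profile without the observation.

Two degenerate-input conventions matter. A stride in which a muscle is
never on contributes amplitude 0 in all regions (with a structured
warning), so amplitude conservation holds only when total on-time is
positive. And a cohort cell with zero SD rejects the profile by default —
on real EMG a zero-variance cell indicates broken data. The exception is
deliberate: *clean synthetic* cohorts produce constitutively saturated
cells (a muscle that is always off in DS2 in every simulated subject),
so `build_normative_profile(..., min_sd =)` optionally floors the SD
instead. The floor never changes a z-score's sign, only its magnitude,
and it is how the pipeline-level tests score synthetic subjects. Totals
are the mean of |z| over the six regions (two totals per muscle); the
absolute value is essential, since opposite-signed deviations must not
cancel.

Pearson correlations between per-muscle totals and covariates (paretic
propulsion, walking speed) use the explicit t-formula with n−2 degrees of
freedom and are cross-checked against `stats::cor.test` in the tests.

## The synthetic generator

Because no gait dataset ships with the package, every pipeline stage is
validated against a parametric generator with analytic ground truth
(`gait_model()`, `simulate_trial()`, `simulate_cohort()`).

*What it emulates.* Strides of fixed duration with per-leg stance
fractions and a contralateral phase lag; vertical GRF as a body-weight
bump with a raised-cosine rise over 30 ms (so a 20 N threshold crossing
sits ~3 ms after true contact) and a mid-stance dip; anterior GRF as one
sine cycle over stance (braking then propulsion), giving a closed-form
propulsive impulse `prop_N * stance_s / π` per stride and hence an
analytic paretic-propulsion value. Muscle envelopes are baselines plus
plateau bursts with raised-cosine shoulders, placed at textbook phasing
for the eight muscles; the hemiparetic preset shifts plantarflexor
activity into first double support and late swing, truncates it before
late single support, extends TA into second double support and weakens
the propulsive bump to 40%. Burst gains jitter lognormally from stride to
stride (SD 0.1), and envelope noise is heteroscedastic — SD proportional
to the signal level with a floor (`noise_sd * max(level, 0.2)`) — because
the amplitude jitter of a rectified, 25 Hz-smoothed envelope scales with
its level; a homoscedastic alternative as wide as the baseline itself
would misrepresent what an envelope is. The ground-truth on/off mask is
the supra-half-amplitude support of each burst (the shoulder midpoint,
3% of the cycle wide by default, ~30 ms at a 1 s stride — the transition
width a 25 Hz smoother produces). True components come from quadrature of
the noiseless waveforms over the analytic region boundaries on a dense
in-stride grid, independent of the pipeline under test. Cohorts jitter
burst centers (±1.5% of cycle), amplitudes and baselines (lognormal),
stance fractions and stride durations per subject; one shared within-trial
noise seed makes a zero-jitter cohort bit-identical.

*What it does not emulate.* Raw interference EMG is optional
(band-limited noise amplitude-modulated by the envelope, for exercising
the filter chain) rather than physiological; there is no electrode noise
structure, no crosstalk between muscles, no fatigue drift, no kinematic
variability within a trial, and the stride clock is metronomic up to the
modeled jitter. Passing the recovery tests therefore shows that the
pipeline is correct *given* gait-locked envelopes and clean force plates;
it does not certify performance on pathological recordings with artifact
contamination, which need the usual laboratory quality control upstream.

A second, component-level generator (`simulate_component_cohort()`) draws
timing/amplitude values cell-wise from Gaussian normative cells,
bypassing signals entirely. It isolates the scoring machinery: scored
against its own leave-in profile, such a cohort should leave roughly the
standard-normal 1.02% of cells outside ±2.57 (slightly fewer, because
leave-in scoring shrinks extremes), which is what the acceptance script
measures.

## Problem sizes and reproducibility

The shipped tests simulate 16–20 s trials at 250–500 Hz sampling with
6-subject pipeline cohorts and a 20-subject (40-leg) component-level
cohort — sizes chosen so the full suite exercises every stage, including
the exact k-means on tens of thousands of samples per channel, while
remaining quick to run; the generator scales to longer trials and higher
rates unchanged. All randomness flows from explicit seeds; the exact
k-means makes the analysis path itself deterministic, so identical
configurations reproduce outputs bit-exactly (the run log records a
config hash alongside the stride count).

## Known limitations

* Amplitude components are shares of the stride's on-envelope integral,
  so they are coupled to total on-time; a muscle that is on longer
  dilutes each region's share. Interpret amplitude scores together with
  timing scores.
* The envelope normalization is relative to walking itself: the method
  cannot distinguish a uniformly weak muscle from a normal one, only
  mis-*patterned* activity.
* Treating two legs of one subject as independent normative observations
  understates between-subject variance slightly.
* Normative windows are task-specific: norms collected at matched
  treadmill speeds do not transfer to substantially different walking
  conditions (slopes, body-weight support, overground turning).
* Event detection is purely kinetic; it requires per-leg force plates
  (e.g. a split-belt instrumented treadmill) and will not segment
  overground strides recorded on a single plate.
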