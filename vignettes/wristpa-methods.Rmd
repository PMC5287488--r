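---
title: "wristpa: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wristpa: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wristpa)
```

This vignette documents the processing model, the choices made where the
design was genuinely open, the numerical details, and what the synthetic
data generator does and does not emulate.

## Gravity autocalibration

During any period in which the device is stationary, the only
acceleration present is gravity, so the measured vector should lie on the
unit sphere. Deviations reveal per-axis offset and gain error. We collect
non-overlapping 10-s windows, aligned to the recording start, whose three
per-axis standard deviations are all below 13 mg, and require (i) at
least 10 such windows and (ii) stationary means beyond ±300 mg on both
sides of zero on every axis — without orientation diversity the sphere
fit is ill-posed.

The fit is iteratively re-projected least squares. A single OLS pass
cannot fit a sphere, so each iteration projects the corrected window
means onto their nearest unit-sphere points, regresses the corrected
value per axis on the projection (adding a centred temperature regressor
when a temperature channel exists), and composes the per-axis linear
maps. Iteration stops when no coefficient moves by more than 1e-9 (a
package choice; the iteration is linearly convergent and this lands well
below measurement noise) or after 1000 iterations. The applied model is
`corrected = (raw - offset) * gain + temp_coeff * (T - Tref)`.

On the parameter count: the model is offset (3) + gain (3), extended by
three temperature slopes *only when the recording carries a temperature
channel*, giving the full 9-parameter autocalibration. Without
temperature, the 6-parameter model is reported and `temp_coeff` is
`NULL`.

Two defensive rules: window statistics ignore windows containing clipped
samples (a clipped rest period is not trustworthy geometry), and a fitted
gain outside (0.5, 2) is treated as uncalibratable rather than applied.
Uncalibratable recordings borrow the most recent prior model for the same
device from the registry, else the next one, else fall back to the
identity with a warning — mirroring how multi-use device fleets are
handled in practice.

## Signal chain

The calibrated samples are linearly interpolated onto an exact uniform
grid (10 ms steps at the 100 Hz default). Raw gaps longer than 5 s are
interrupts: grid points strictly inside them are missing, never
interpolated. The Euclidean norm is taken first and the 20 Hz 4th-order
Butterworth low-pass is applied to the scalar magnitude afterwards,
following the stated processing order of the protocol this package
implements (filtering per axis before the norm is a defensible
alternative; the difference is confined to machine-noise rectification
effects).

Filtering is zero-phase: one forward and one backward pass, each
initialised at the filter's steady state for the segment's first/last
value. Consequences worth stating:

* DC gain is exactly 1 (a constant segment is reproduced to machine
  precision).
* The cutoff attenuation is the *squared* single-pass response: 0.5
  rather than 1/√2. This is intentional and tested; zero-phase filtering
  avoids smearing epoch boundaries with group delay.
* Each contiguous non-missing segment is filtered independently; missing
  runs are never bridged (the 5-s rule already decided what is missing).
  Segments shorter than three filter orders pass through unfiltered with
  a warning — too short for the filter to settle, and at most 120 ms of
  data at the default rate.

Gravity removal offers three variants, all in mg: truncated ENMO
`max(VM - 1, 0) * 1000` (the primary metric), absolute ENMO
`|VM - 1| * 1000`, and a rectified high-pass of VM. The high-pass cutoff
is not specified by the protocol; we use 0.2 Hz (configurable), below
locomotor frequencies but high enough to remove the gravity DC. On
simulated cohorts the weekly means of the three variants correlate above
0.95, which is the property that matters for association studies.

## Epochs, non-wear, imputation

Epochs are 5-s means aligned to the *local* wall clock from midnight —
all diurnal constructs (imputation slots, hour bins, quadrants) are
wall-clock phenomena, so timestamps are carried as UTC plus a fixed local
offset. Partial first/last epochs are dropped. Epochs with a positive
but incomplete valid fraction keep the mean of their valid samples
(threshold-free; the simplest unbiased choice). Daylight-saving
transitions are not re-normalised: civil-time labels are used as-is, one
duplicated or missing hour per transition.

Non-wear is a maximal run of consecutive, gap-free stationary windows
spanning at least 60 minutes (boundary inclusive). Epochs overlapping an
episode are non-wear; they and fully-missing epochs are imputed with the
mean worn value in the same 1-min time-of-day slot on the other
measurement days. The protocol gives no fallback for slots worn on no
other day, so: widen the pool to ±30 min around the slot (other days
only), then fall back to the participant's overall worn mean; epochs
filled by either fallback carry an extra flag. Worn epochs are never
modified — this is asserted bitwise in the tests.

The intensity distribution is the cumulative time at or below each 5-mg
breakpoint from 0 to 2000 mg, over worn *plus imputed* epochs ("all
available" epochs is ambiguous between worn-only and worn+imputed; we
impute both the value and its distribution contribution, configurably).
Epochs above 2000 mg are top-coded into the final bin so the curve
saturates exactly at the total time.

Inclusion requires at least 72 h of (pre-imputation) wear and at least
one worn epoch in each of the 24 hour-of-day bins.

## Summaries and the reliability simulation

Participant profiles (overall, hourly, quadrant, weekday/weekend) average
worn plus imputed epochs; wear time counts worn epochs only. Season is
assigned from the first worn day (start-of-wear rather than midpoint —
the choice is unstated in the protocol and rarely differs) with
meteorological boundaries, Spring = 1 March. Cohort tables report
wear-time median/IQR and activity mean/SD per sex × age band (45–54
through 75–79) and Cohen's d (pooled SD) for sex within band and adjacent
bands. When reproducing published worked examples the rounded published
stratum statistics are used as inputs, full precision otherwise.

The minimum-wear-time simulation asks how long a wear period is needed
for a stable weekly measure: for each duration *h* in {24, ..., 168} h,
random contiguous *h*-hour sub-windows are drawn from fully compliant
participants (10 replicates per participant per duration, wrap-free,
fixed seed), the outcome is recomputed with the usual imputation, and the
ICC between truncated and full outcomes across participants is averaged
over replicates. The ICC flavour is unstated in the protocol; we use the
two-way random-effects, absolute-agreement, single-measurement form
ICC(A,1), computed from the mean-square decomposition (and cross-checked
in the tests against an independent `aov()`-based computation). At
*h* = 168 the two measurements coincide and the ICC is 1 by construction;
degenerate zero-variance tables return 1 when the columns are identical
and `NA` otherwise.

## The synthetic generator

`simulate_participant()` builds a week as alternating rest and activity,
hour by hour:

* **Orientation** is a point on the unit sphere, parameterised by two
  angles. During activity the angles follow a slow random walk (per-axis
  wrist wobble of a few tens of mg per 10-s window — enough that wear
  windows are never stationary); during each hour's single mid-hour rest
  bout and during non-wear the orientation is frozen. Because the
  orientation always has unit norm, the vector magnitude is exactly
  `1 + a(t)` whatever the orientation does.
* **Activity** `a(t)` is rectified band-limited (0.5–10 Hz) Gaussian
  noise, rescaled within each hour so the realised hourly mean equals the
  target diurnal profile exactly. The default profile has six-hour
  quadrant means of 4.4 / 38.6 / 44.3 / 26.4 mg (overall 28.4 mg),
  matching published large-cohort wrist summaries; cohort simulation
  scales it per participant from age-band normals (31 / 29 / 26.5 /
  23.5 mg, SD 8 mg).
* **Rest structure**: one contiguous rest block per hour covering
  `rest_fraction` of it (default 0.5), placed mid-hour so stationary runs
  can never reach the 60-min non-wear threshold during wear. Rest bouts
  supply the calibration geometry: one random orientation per hour, ~168
  orientations per week.
* **Degradations**: per-axis white sensor noise (default 5 mg during
  wear, a realistic noise floor for this device class; 3 mg while lying
  still during non-wear), invertible miscalibration
  (`stored = true / gain + offset`), sample deletion for interrupts, and
  driven clips.

Ground truth records the embedded offset/gain, the non-wear intervals,
and the intended overall and hourly means. Note one known bias: sensor
noise on the unit-norm rest signal survives truncation asymmetrically
(E[max(N(0, σ'), 0)] = σ'/√(2π) after filtering), adding roughly 2% to
the recovered weekly mean at the default noise level — which is why
end-to-end recovery is asserted at 5%, not at the imputation-level 2%.

What the generator does **not** emulate: biomechanically realistic gait
spectra, device temperature physics, orientation-dependent noise,
autocorrelated non-wear behaviour, or between-axis noise correlation.
Passing tests therefore demonstrate the correctness of the processing
chain's logic and its statistical behaviour under controlled violations —
not validity of the metric on free-living human data.

For the reliability study only epoch-scale structure matters, so
`simulate_epoch_cohort()` generates fully worn epoch series directly:
participant levels (SD 8 mg between persons), multiplicative day effects
(log-scale SD 0.2) and gamma epoch noise (CV 0.5). Without day-to-day
variation the truncation study would be trivially perfect; these values
give ICC ≈ 0.86 at 24 h rising to 1 at 168 h, the qualitative shape that
motivates a 72-h minimum.

## Problem sizes and test scaling

The algorithms are rate-agnostic: every constant lives in
`pipeline_config()`, and the test suite exercises the chain at 5–25 Hz
with the low-pass cutoff held at the same 0.4 × Nyquist fraction as the
100 Hz default (filter-response assertions always run at 100 Hz/20 Hz).
Sizes used by the tests and the acceptance script: 50 simulated devices
× 150 stationary windows for calibration recovery; 20 half-day
participants at 10 Hz for non-wear detection; one 7-day participant at
10 Hz for end-to-end recovery; a 200-participant, 60-s-epoch cohort for
the reliability curve; a 20-participant, 1-day, 25 Hz cohort for the
three-metric correlation.

## Known limitations

* Calibration assumes enough orientation diversity during natural rest;
  the borrowing fallback assumes device-stable (not wearer-stable)
  miscalibration.
* The non-wear rule cannot distinguish a genuinely motionless worn wrist
  (> 60 min) from non-wear; conversely the imputation assumes missingness
  is non-informative given time of day.
* Epoch means of a rectified signal retain a noise-dependent positive
  bias at very low activity; comparisons across devices with different
  noise floors should calibrate for it.
* The civil-time handling tolerates DST duplication rather than
  re-projecting onto a 24-h circle.
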