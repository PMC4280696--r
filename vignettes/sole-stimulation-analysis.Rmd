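---
title: "Detecting reflexes and ankle movement from mechanical foot-sole stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reflexes and ankle movement from mechanical foot-sole stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solereflex)
```

## The problem this package addresses

For patients on bed rest after neurological injury, gait training can begin
in a supine position, but effective training needs the foot sole to feel
ground-reaction-like loads. A pneumatic shoe platform can press plates
against the heel and the forefoot with adjustable pressure (2--3.5 bar,
forces of 100--280 N) and adjustable rise time (0.05 s "fast", 0.2 s
"slow"). Loading the sole, however, can evoke reflexes in the lower-leg
muscles — tibialis anterior (TA) and soleus (SOL) — and a strong,
fast-rising stimulus can evoke withdrawal-like double-burst reflexes that
visibly perturb the ankle. Choosing stimulation parameters therefore
requires quantifying, per stimulus: did a reflex occur, how large was the
EMG response, and how much did the ankle move?

`solereflex` implements that analysis as a tested pipeline:

* **Protocol models** — the plate force–pressure calibration, trapezoidal
  force profiles, the randomized single-pulse protocol (4 pressures x 2
  rise speeds x 2 locations x 4 repetitions, one 0.8 s pulse every 30 s)
  and the cyclic walking-like pattern (heel loaded over 0--40% of the gait
  cycle, forefoot over 20--60%).
* **EMG processing** — band-pass 5--500 Hz, 50 Hz notch, full-wave
  rectification; MVC normalization; baseline mean + SD reflex threshold
  with a 10 ms duration criterion; occurrence and RMS summaries.
* **Kinematics** — the sagittal ankle angle from three markers by the law
  of cosines, two-stage smoothing, plate-induced angle change and
  perturbation detection.
* **Statistics** — per-subject aggregation and paired one-sided t-tests,
  with the bundled ten-subject reference tables.
* **Synthetic sessions** — a generator that produces EMG, marker and
  trigger series with known ground truth, so every stage is testable
  without human recordings.

## The detection model

EMG is sampled at 1200 Hz. After zero-phase filtering (4th-order
Butterworth band-pass 5--500 Hz; biquad notch at 50 Hz, quality factor 30)
and rectification, the reflex criterion for a stimulus at onset $t_0$ is:

1. **Threshold.** Over the 0.8 s before $t_0$, compute the mean $\mu$ and
   sample SD $\sigma$ of the rectified signal; the threshold is
   $\mu + \sigma$.
2. **Duration.** A reflex occurred iff the rectified signal stays strictly
   above the threshold for at least 10 ms — 12 consecutive samples at
   1200 Hz — within the 0.8 s stimulation window.
3. **Double burst.** Two qualifying runs separated by at least 20 ms below
   threshold are reported as a double burst.

The baseline statistics are computed on the *rectified* signal, not the
signed one, so threshold and burst live on the same scale: the mean of a
signed zero-mean EMG baseline is approximately zero, which would reduce the
threshold to the SD alone and make it dimensionally inconsistent with a
rectified burst. A `domain = "raw"` option in `baseline_stats()` preserves
the signed reading for comparison.

Amplitudes are normalized to the MVC reference: the maximum over three
maximal-voluntary-contraction trials of the RMS in a 500 ms window centred
at each trial's maximal rectified sample. Responses are reported in
%MVC\_RMS — the RMS over the 0.8 s stimulation window for single pulses,
or the ratio of stimulation-window RMS to a 5 s pre-stimulation rest for
cyclic loading.

Zero-phase (forward–backward) filtering is used throughout so that burst
onset latencies are not shifted by filter group delay.

## The ankle-angle model

Markers sit at the medial knee $(x_k, y_k)$, medial ankle $(x_a, y_a)$ and
first metatarsal head $(x_m, y_m)$, sampled at 100 Hz in the sagittal
plane. With segment lengths $L_{ka}$, $L_{am}$, $L_{km}$ (Euclidean
distances), the shank–foot angle at the ankle is

$$\theta_a = \arccos\!\left(\frac{L_{ka}^2 + L_{am}^2 - L_{km}^2}
{2\,L_{ka}L_{am}}\right).$$

Dorsiflexion decreases $\theta_a$, plantarflexion increases it; the neutral
supine posture is about 150°. An alternative convention that adds 180° to
the arc-cosine is also implemented (`convention = "printed_offset"`),
because the formula circulates in both forms; the interior reading is the
default since a supine neutral posture of ~150° and the stated
direction of dorsiflexion are only consistent with an interior angle, which
by construction lies in (0°, 180°]. Every angle series records which
convention produced it, so downstream output is never ambiguous.

Motion traces are smoothed in two stages: a centred moving average of
window 5 samples (a running median is available for spike-like artifacts),
then LOESS local linear regression with a default span of 0.1. Both stages
preserve constants and, away from the edges, linear trends, so ramp-and-hold
plate excursions survive smoothing.

The plate-induced change for one stimulus is the mean angle over the final
0.2 s of the stimulus (the plate is fully extended after at most 0.2 s, so
this plateau excludes the ramp) minus the mean over the 0.5 s before onset.
A reflex-induced perturbation is flagged when the residual against an
idealized ramp-and-hold fit exceeds 0.5° in magnitude for at least 50 ms
during the stimulus: a 1° excursion — the size seen with strong
withdrawal-like reflexes — is then unambiguously flagged, while smoothing
residuals (well under 0.2° at the modelled jitter) are not.

`analyze_angle_changes()` extracts one segment per event and ends it at the
event offset deliberately: LOESS near a boundary uses a one-sided window,
and stopping at the offset keeps the plate's retraction out of the plateau
estimate, which would otherwise bias the change toward zero by up to a few
tenths of a degree.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass edges | 5, 500 | Hz | analysis band of surface EMG at 1200 Hz |
| notch | 50 (Q = 30) | Hz | mains interference |
| baseline window | 0.8 | s | matches the stimulus duration, immediately pre-onset |
| duration criterion | 0.010 | s | 12 samples at 1200 Hz; strict inequality at the threshold |
| double-burst gap | 0.020 | s | minimum below-threshold separation of two bursts |
| MVC window | 0.5 | s | RMS window centred at the maximal rectified sample |
| smoothing window | 5 | samples | first-stage noise removal of 100 Hz marker traces |
| LOESS span | 0.1 | fraction | second-stage smoothing; degree-1 local fits |
| baseline / plateau windows | 0.5 / 0.2 | s | angle change estimation around the ramp |
| perturbation criterion | 0.5° for 0.05 s | — | flags 1° excursions, ignores smoothing residuals |
| outlier flag | 5 x median baseline SD | — | automated stand-in for visual screening |

The outlier flag replaces visual inspection of noisy trials with a
reproducible rule: a trial is excluded when its baseline SD exceeds five
times the session median. It is logged per trial (`keep` column) and
configurable.

## What the synthetic generator emulates

`subject_profile()` + `gen_session()` produce a complete session with
ground truth:

* **Baseline EMG**: band-limited (5--500 Hz) Gaussian noise calibrated so
  the rectified RMS equals the rest level (defaults 1.26 µV TA, 1.32 µV
  SOL, the bundled ten-subject means).
* **Reflex bursts**: Bernoulli-drawn per stimulus. The draw probability
  rises with pressure and is multiplied by `fast_multiplier` for fast
  stimuli; the burst amplitude (in %MVC\_RMS) is linear in pressure through
  `reflex_gain` — qualitatively matching "higher and faster forces evoke
  larger responses" without asserting a specific functional form. Bursts
  are tapered-cosine-windowed band-limited noise whose carrier magnitude is
  floored at 55% of the envelope, then shaped by the analysis-band filters
  and peak-scaled. The floor makes the rectified burst track its envelope,
  so the 10 ms duration criterion responds to the commanded burst duration
  rather than to carrier zero crossings; the pre-shaping keeps the peak
  stable through the pipeline's own filtering instead of ringing above it.
  Double bursts use a 100 ms separation — well above the 20 ms criterion,
  because the narrow notch filter rings for tens of milliseconds past a
  burst and would otherwise blur the gap.
* **Markers**: fixed knee and ankle, metatarsal rotated so the angle
  follows a ramp-and-hold of −1.33° (heel) / +1.07° (forefoot, the
  bundled-table means) per event, 0.1 mm jitter, plus an optional 1°
  transient for susceptible subjects under fast high-pressure stimuli.
* **Ground truth**: every draw, amplitude, angle change and perturbation is
  recorded per event. The 60 ms reflex latency is a placeholder — no
  measured latency backs it — and is labelled as such
  (`latency_is_placeholder`).

What it does **not** emulate: motor-unit physiology, muscle-specific
latencies, fatigue, movement artifacts, electrode lift-off, or the
between-subject heterogeneity visible in the reference tables (a profile is
one "subject"). Passing recovery tests on synthetic sessions therefore
demonstrates that the pipeline measures what the generator encodes — a
self-consistency guarantee, not evidence about real recordings.

## Numerical choices and degenerate inputs

* Windows are half-open `[start, end)`; window lengths in samples are
  `round(duration x rate)`.
* The arc-cosine argument is clipped to [−1, 1] within 1e−9; a larger
  excursion is a geometry error, as are coincident markers.
* The threshold comparison is strict: a signal exactly at threshold never
  counts.
* Table display uses round-half-away-from-zero at 2 decimals (so a mean of
  189.155 prints as 189.16); JSON output keeps full precision.
* Force interpolation between calibrated pressures is linear (the
  calibration is exactly linear at 80 N/bar heel, 50 N/bar forefoot);
  extrapolation outside 2--3.5 bar is an error.
* The trapezoid's fall time defaults to its rise time; the platform does
  not control retraction speed, so no measured value exists.
* A paired t-test on zero-variance differences is an explicit error rather
  than a silent NaN.

## Problem sizes used in tests

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to keep every stochastic check comfortably inside its
statistical tolerance: occurrence recovery uses 200 repetitions of one
stimulus type (3 s spacing rather than the protocol's 30 s — the spacing
only pads rest time and does not interact with per-trial baselines beyond
the 0.8 s they need), angle recovery uses 12 trials per location, and
perturbation checks use 8 susceptible plus 24 control trials. At 200
repetitions the binomial 3-SE band around a generating probability of 0.25
is ±9.2 percentage points.

## A worked example

```{r example, eval = FALSE}
prof <- subject_profile(reflex_probability = 0.5)
sch <- single_pulse_protocol(seed = 42)       # 16 types x 4 reps, 0.8 s / 30 s
ses <- gen_session(prof, sch, seed = 1)

mvc <- list(TA = mvc_reference_from_value("TA", prof$mvc_rms[["TA"]]),
            SOL = mvc_reference_from_value("SOL", prof$mvc_rms[["SOL"]]))
trials <- analyze_single_pulse(ses$emg, ses$schedule, mvc)
occurrence_by_type(trials)

angles <- analyze_angle_changes(ses$markers, ses$schedule)
aggregate(change_deg ~ location, angles, mean)
```

## Known limitations

* The perturbation magnitude is measured after smoothing, which attenuates
  a 0.2 s transient by roughly 20--25%; the flag is calibrated for that,
  but the reported magnitude under-states the raw excursion.
* Occurrence scoring assumes the schedule's trigger timing is exact;
  hardware latency between trigger and plate contact is not modelled.
* The cyclic analysis reports a single stimulation/rest RMS ratio;
  per-plate attribution during the overlapping mid-stance window is not
  attempted, and per-event angle changes in cyclic schedules superimpose
  both plates' excursions.
* Reported reflex latencies are provided for completeness but have no
  reference values to validate against.
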