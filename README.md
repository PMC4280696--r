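# solereflex

Analysis of mechanical foot-sole stimulation: reflex EMG detection, ankle
kinematics, and per-subject statistics for pneumatic shoe-platform
protocols.

## The problem

Supine gait training for bed-rest patients needs walking-like loads on the
foot sole. A pneumatic platform presses plates against the heel and the
forefoot (2–3.5 bar, 100–280 N, rise time 0.05 s "fast" or 0.2 s "slow"),
either as isolated 0.8 s pulses or as a cyclic walking-like pattern (heel
over 0–40 % of the gait cycle, forefoot over 20–60 %). Loading the sole can
evoke reflexes in the tibialis anterior (TA) and soleus (SOL); fast,
strong stimuli can trigger withdrawal-like double-burst reflexes that
perturb the ankle. The analysis question: for each stimulus, did a reflex
occur, how large was the response, and how far did the ankle move?

`solereflex` is for researchers in neurorehabilitation and
electrophysiology who need that pipeline as tested, scriptable code.

## The model

* **Reflex detection.** EMG (1200 Hz) is band-pass filtered 5–500 Hz,
  notch-filtered at 50 Hz (zero-phase), and full-wave rectified. For a
  stimulus at onset *t₀*, the threshold is *μ + σ* of the rectified
  baseline over the 0.8 s before *t₀*; a reflex occurred iff the signal
  stays strictly above threshold for ≥ 10 ms (12 consecutive samples)
  within the stimulation window. Two qualifying bursts ≥ 20 ms apart are a
  double burst.
* **Normalization.** Amplitudes are expressed in %MVC_RMS: the RMS in a
  500 ms window centred at the maximal rectified sample, maximized over
  three maximal-voluntary-contraction trials.
* **Ankle angle.** From markers at the knee, ankle and first metatarsal
  head, θₐ = arccos((L²ₖₐ + L²ₐₘ − L²ₖₘ)/(2 Lₖₐ Lₐₘ)); dorsiflexion
  decreases θₐ, neutral ≈ 150°. Plate-induced change = plateau mean minus
  pre-onset baseline mean after window-5 + LOESS smoothing; residuals
  > 0.5° for ≥ 50 ms against a ramp-and-hold fit flag a reflex-induced
  perturbation.
* **Statistics.** Per-subject summaries aggregate to Mean ± SD rows;
  paired one-sided t-tests (fast > slow) with t = mean(d)/(sd(d)/√n),
  df = n − 1.

A synthetic-session generator (`gen_session()`) produces EMG, marker and
trigger series with recorded ground truth, so the whole pipeline is
testable without human-subject data. Ten-subject reference tables (rest and
MVC EMG, slow/fast response amplitudes, angle changes, occurrence
percentages) ship with the package (`reference_table()`).

## Worked example

```r
library(solereflex)

prof <- subject_profile(reflex_probability = 0.5)   # one synthetic subject
sch  <- single_pulse_protocol(seed = 42)            # 16 stimulus types x 4 reps
ses  <- gen_session(prof, sch, seed = 1)

mvc <- list(TA  = mvc_reference_from_value("TA",  prof$mvc_rms[["TA"]]),
            SOL = mvc_reference_from_value("SOL", prof$mvc_rms[["SOL"]]))
trials <- analyze_single_pulse(ses$emg, ses$schedule, mvc)
occ <- occurrence_by_type(trials)
head(occ[occ$muscle == "TA", -1], 4)
#>   location rise_speed pressure occurrence_pct
#> 2 forefoot       fast        2            100
#> 4     heel       fast        2            100
#> 6 forefoot       slow        2              0
#> 8     heel       slow        2              0

angles <- analyze_angle_changes(ses$markers, ses$schedule)
aggregate(change_deg ~ location, angles, function(x) round(mean(x), 2))
#>   location change_deg
#> 1 forefoot       1.07
#> 2     heel      -1.32
```

Fast stimuli are detected on every repetition, while the weak bursts evoked
by slow 2 bar stimuli (≈ 1.6 %MVC at the default gains) stay below the
baseline threshold — the same asymmetry between fast and slow stimulation
the platform studies report. Heel loading dorsiflexes the ankle (negative
change), forefoot loading plantarflexes it.

The bundled per-subject tables reproduce the published group comparison:

```r
slow <- reference_table("slow_rms_pct")
fast <- reference_table("fast_rms_pct")
paired_t_one_sided(slow$heel_ta, fast$heel_ta)
#> Paired one-sided t-test (fast > slow): t = 3.204, df = 9, p = 0.0054
```

A thin CLI over the same functions lives in `inst/scripts/solereflex.R`
(`simulate-protocol`, `simulate-session`, `kinematics`, `detect`,
`report`).

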