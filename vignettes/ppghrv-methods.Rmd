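---
title: "Methods: from wrist PPG to day-wise autonomic comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist PPG to day-wise autonomic comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`ppghrv` implements a complete analysis chain for studying how a
pharmacological exposure — the motivating case is an antenatal corticosteroid
course given as two injections 24 h apart — changes maternal autonomic
regulation as seen through wrist photoplethysmography (PPG):

1. **Segment selection.** From a continuous 32 Hz PPG stream, one contiguous
   5-minute segment is chosen per study day, inside a ±4 h band around the
   daily target (1 h before the first injection for day 0; 24/48/72/96 h
   after it for days 1–4). Day-0 and day-1 windows must end before the first
   and second injections. A segment qualifies only if at most 20% of its
   inter-pulse intervals (IPIs) are discarded by the artifact rules.
2. **IPI extraction.** Pulse troughs are detected, IPIs formed as trough-to-
   trough differences, implausible intervals rejected (outside 0.4–2.0 s, or
   differing more than 20% from the preceding interval), and rejected
   intervals replaced by natural cubic-spline interpolation for the features
   that need a gap-free series.
3. **HRV features.** Thirteen per-segment features: HR; SDNN, RMSSD, pNN50;
   total power, LF (0.04–0.15 Hz), HF (0.15–0.40 Hz), LF/HF; Poincaré SD1,
   SD2, SD1/SD2; sample entropy (m = 2, r = 0.2·SD); DFA α₁ over 4–16 beats.
4. **Pulse-wave morphology.** Each accepted pulse is segmented between
   troughs; fiducial points are located on the waveform (IT, SP, FT), its
   first derivative (a1, b1, end-diastolic velocity) and second derivative
   (a2, b2, e2); 35 amplitude/time/area/velocity/ratio/slope/angle features
   are computed per pulse and aggregated to the segment median; per-day
   ensemble-average pulses visualise morphology change.
5. **Statistics.** HRV uses a within-subject design: baseline (day 0, else
   day 4) versus days 1–3, Friedman omnibus, Dunn post hoc with Bonferroni
   correction, and bootstrap Cohen's *d* (10,000 iterations, percentile 95%
   CI). Morphology uses an unpaired Kruskal–Wallis across all five days with
   the same post hoc machinery.

Because the patient recordings behind this design are not publicly
deposited, the package ships a first-class synthetic cohort generator with
known ground truth, so that every stage is testable end to end.

## The synthetic world

### Pulse model

A pulse is a sum of Gaussian lobes: a narrow systolic lobe (peak at
2·`systolic_width` after onset, σ = ⅔·`systolic_width`), a wider "decay
shoulder" at 45% of the systolic amplitude that makes the falling limb
slower than the rise, and a delayed diastolic lobe standing in for the
dicrotic/diastolic limb. Everything on the support is a plain Gaussian sum,
so the waveform and its first two derivatives are available in closed form —
that is what lets the test suite compare every morphology feature against a
symbolic oracle. The template is causal (zero before onset), which pins the
local minimum between beats to the next beat's onset; trough-based interval
extraction then has an exact ground truth. An earlier design used a single
asymmetric Gaussian with a σ-switch at the peak, but its second derivative
is discontinuous there and grid-sensitive, which is why the shoulder
formulation was adopted.

### Beat intervals

IPIs are generated as mean + sinusoidal LF and HF modulation + white noise,
with the beat time driving the modulation phase. Band powers of the ground
truth are then known in closed form (a sinusoid of amplitude *a* carries
*a*²/2). Defaults: maternal baseline HR ~ N(85, 7) bpm (hospitalized
pregnant women run higher than the general population), LF amplitude 15 ms
at ~0.095 Hz, HF amplitude 25 ms at ~0.25 Hz, 10 ms white noise. These were
chosen once as field-typical values and not revisited.

### Day-to-day variability and effects

Real repeated measurements differ between days even without any drug:
circadian phase, posture and state all move HR and HRV. The generator
therefore adds day-level jitter (HR ± 3 bpm SD; log-normal 15% on modulation
amplitudes; log-normal 10% on pulse amplitude). Without it, injected effects
would be detected with physically implausible effect sizes. Day effects are
knobs, not constants: `reference_day_effects()` mimics the reported
post-drug pattern (+10 bpm and halved HF modulation on day 1, recovering
over days 2–3, pulse amplitude shrinking monotonically to day 4), while
`null_day_effects()` gives an exchangeable null. One known side effect: an
HR shift slightly re-shapes how broadband interval noise maps into the LF
band, so with 57 paired participants even the LF omnibus test can reach
significance under the reference effects although LF modulation itself is
untouched — at real-world day-to-day noise this is harmless, but it is worth
knowing when interpreting green tests.

### Cohort structure

Defaults reproduce the study's shape: 61 participants, of whom exactly
`round(61 · 8/61) = 8` carry a pre-injection day-0 recording (most women
have already received their first injection when monitoring starts; the
others use day 4 — ≈ 2.5 half-lives after the second injection — as a
washout baseline). Structured missingness removes one post-baseline day from
each of four designated participants so that 57 of 61 are complete for the
paired analysis. The published per-day morphology counts (8/60/60/56/53)
cannot be reproduced exactly by any single missingness pattern that also
yields 57 complete paired participants; they additionally reflect
fiducial-detection losses that the source material does not quantify, so
they are treated as analysis output, not generator input.

### Artifacts

Two failure modes of wrist PPG are emulated structurally: motion bursts
(additive broadband noise, default 0.2/min for 2 s) and sensor detachment
(constant signal, default 1/h for 10 s). No quantitative artifact burden is
published for the motivating study; these defaults are illustrative, and the
clean-signal path (`artifacts = NULL`) is what the recovery guarantees are
stated on.

## Numerical choices

* **Trough detection.** The published detector the study cites is not
  described in its text, so the contract — one trough per beat on clean
  signal, within 2 samples of the true beat onset, none closer than 0.4 s —
  defines correctness rather than a specific algorithm. The native detector
  band-passes at 0.5–8 Hz with forward–backward second-order Butterworth
  sections (closed-form biquads; no external filtering dependency), takes
  derivative sign-change minima, gates them by local pulse amplitude
  (silencing flat detachment stretches), applies a 0.4-s refractory rule
  keeping the deeper competitor, and refines each trough on the lightly
  smoothed raw signal.
* **Discarded fraction.** The quality gate and the IPI series share one
  number. The fraction is gap-aware: an invalid interval spanning several
  missed beats (detachment) is charged as the number of beats it swallowed,
  and uncovered time at segment edges is charged likewise; on ordinary
  segments this reduces exactly to `1 − n_valid/n_raw`. A purely count-based
  fraction would pass a segment that is 30% flatline with a single rejected
  interval, which is clearly against the intent of the 20% gate.
* **20% rule predecessor.** "Differing from the preceding interval by more
  than 20%" is ambiguous when the predecessor was itself rejected. The
  default compares against the nearest preceding *valid* interval, which
  stops one outlier from cascading; `predecessor = "raw"` is available.
  The first interval is judged on the range rule alone.
* **Spectra.** The IPI tachogram (gap-filled, in ms) is spline-resampled to
  4 Hz, linearly detrended, and Welch-averaged (120-s Hann segments, 50%
  overlap). Total power integrates 0.003–0.40 Hz, a 5-minute convention;
  the source material does not define "total power", name an estimator, or
  give a resampling rate, so these are recorded configuration. SDNN uses the
  sample (n−1) SD. RMSSD/pNN50/Poincaré successive differences pair only
  intervals adjacent in the original beat sequence — a difference across a
  rejected interval is not a physiological succession.
* **Sample entropy** returns 0 on a zero-variance series (the tolerance
  r = 0.2·SD would be zero and the statistic degenerate); this avoids NaNs
  poisoning cohort tables and is logged. Fewer than 50 intervals, or no
  template match, give `NA`.
* **DFA** uses non-overlapping boxes and first-order detrending, the
  original formulation, over boxes of 4–16 beats.
* **Morphology derivatives** are central differences after a 3-point moving
  average (second-derivative fiducials are noise-sensitive at wearable
  sampling rates). The smoother pads its ends by quadratic extrapolation so
  the smoothing bias is uniform; endpoints use second-order one-sided
  stencils. Without both, endpoint features (systolic foot velocity, mean
  acceleration, pulsatility index) carry a few-percent bias that the
  symbolic-oracle tests expose.
* **Morphology conventions.** Widths at X% of the pulse amplitude are
  measured above the IT baseline with sub-sample level-crossing
  interpolation, and the reported ratio is diastolic/systolic (the feature's
  name), resolving a label-versus-prose conflict in the source table. Areas
  are trapezoids above the straight IT–FT baseline so slow drift does not
  leak in. End-diastolic velocity is the first derivative at FT. e2 is the
  highest second-derivative local maximum after b2 and before 80% of the
  pulse duration. Angles normalise amplitude to the pulse amplitude, keep
  time in seconds, and are reported in degrees; raw-unit angles would be
  device-dependent. b2 amplitude is reported as an absolute value and the
  b2/a2 ratio uses it; e2/a2 is signed. Per-segment aggregation is the
  median. Ensemble pulses are resampled to a 100-point grid over each
  pulse's own IT–FT span (relative time), with amplitudes deliberately not
  normalised so day-to-day attenuation stays visible.
* **Statistics.** Friedman and Kruskal–Wallis use tie-corrected mid-rank
  formulas (validated against base R's implementations); Dunn contrasts use
  pooled-rank z statistics with tie correction (unpaired) or mean within-row
  ranks with SE √(k(k+1)/6n) (paired); Bonferroni multiplies by the number
  of contrasts within one feature's panel (6 paired, 10 unpaired), not
  across features. Paired Cohen's *d* is mean(difference)/SD(difference);
  bootstrap CIs are percentile, 10,000 iterations by default, seeded.
* **Candidate windows** are enumerated on a 30-s grid anchored on the target
  time, ordered by distance to target with earlier-start tie-breaks, so
  selection is deterministic and the day-0 rule ("as close to 1 h before the
  first injection as possible") falls out of the ordering. A tolerance
  smaller than the window length still admits the window starting exactly at
  the target.

## What a green test does and does not establish

The synthetic world has a parametric pulse, sinusoidal modulation, and
stylised artifacts. Green acceptance tests establish that the pipeline
recovers what was injected — beat times, band powers, day-wise HR shifts, HF
suppression, amplitude attenuation — and that every estimator matches an
independent oracle on its own definition. They do not establish clinical
validity on real wrist PPG: real pulses vary in shape within a participant,
artifacts are not white, modulation is not sinusoidal, and posture effects
correlate with time of day. The published per-day IPI-rejection medians
(2.4–3.6%) come from such real data; clean synthetic signals sit below 2%
by design, and no attempt is made to tune the artifact model to reproduce
the published medians.

## Known limitations

* Segment selection is fully automated; the original analysis picked
  segments manually, by unstated criteria, so the two can legitimately
  differ on noisy days.
* 32 Hz sampling quantises second-derivative fiducials; the feature
  definitions are validated at 1 kHz against the symbolic oracle, while at
  32 Hz only fiducial *times* (to 2 samples) are guaranteed.
* The day-1 LF side effect of HR shifts described above.
* No accelerometer channel is synthesised and no motion-guided masking is
  implemented; artifact handling rests entirely on the IPI rejection rules
  and the 20% gate.
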