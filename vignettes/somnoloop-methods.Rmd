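---
title: "somnoloop: models, design choices, and what the synthetic benchmarks show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnoloop: models, design choices, and what the synthetic benchmarks show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

somnoloop implements the computational stack of a headband-style sleep-aid
wearable: real-time four-stage sleep scoring (wake W, light sleep LS, deep
sleep DS, REM) from six dry-electrode ExG channels plus PPG and
accelerometry, and a closed-loop acoustic-stimulation controller that reacts
to the scored stream. Because the clinical recordings such devices are
validated on are not redistributable, the package ships a synthetic
polysomnography simulator as a first-class, tested module; every benchmark
in the test suite and in `scripts/acceptance.R` runs against it. This
vignette explains the models, the tunable parameters, and — importantly —
what passing those benchmarks does and does not demonstrate about real
recordings.

## The scoring pipeline

One 30-s epoch at a time (0-based indices, half-open windows
`[30i, 30i + 30)`; trailing partial epochs are discarded):

1. **Channel quality.** Each epoch x channel cell is screened for
   flatline fraction, rail-saturation fraction, high-amplitude 1-s windows,
   implausible RMS (outside 0.5–150 µV), and mains-band (45–55 Hz) power
   relative to the 0.3–35 Hz band. A cell is scorable iff no screen fires.
   Thresholds live in `quality_thresholds()` and are deliberately ordinary
   artifact screens: the goal is a deterministic, auditable rule, not a
   learned detector.
2. **Dynamic re-referencing.** Targets FH_L/FH_R/OTE_L/OTE_R are
   re-referenced per epoch with a fixed fallback chain: contralateral bone
   electrode (BE) if usable, else ipsilateral BE, else the raw channel. The
   alternative schemes (`contralateral_be`, `none`) are kept for
   comparison; the chain ordering makes the dynamic scheme agree with the
   contralateral scheme whenever all channels are clean, and guarantees it
   never yields fewer derived channels.
3. **Features.** Welch power spectra (4-s Hann segments, 50% overlap) give
   absolute and relative power in the Delta/Theta/Alpha/Beta bands
   (0.5–4/4–8/8–13/13–30 Hz); hallmark events come from envelope-threshold
   spindle detection (11–16 Hz, 3x median envelope, 0.5–2 s) and
   zero-crossing slow-wave segmentation (0.3–2 Hz, trough >= 40 µV,
   0.25–3 s); EOG and EMG summaries use the 0.3–4 Hz forehead band and the
   20–30 Hz band respectively. The EMG band stops well below the ~100 Hz
   content a muscle signal can carry because the adopted 0.3–35 Hz
   reference chain (and any 200 Hz recording) cannot represent it; the band
   is configurable for wider-band chains.
4. **Classifiers.** The primary (PML, ExG-feature) and secondary (SML,
   vitals-feature) models are multinomial logistic regressions
   (`nnet::multinom`) with inverse-class-frequency weights. The family was
   chosen because it exposes calibrated class probabilities and an exact
   warm-start mechanism (initial weights), which is what the pre-training
   experiment needs; it is not a claim about the original device's
   architecture, which is not public. Warm starts reuse the pre-trained
   model's feature standardization so weights remain comparable.
5. **Fusion and smoothing.** In real time, an epoch is scored by the PML
   when any ExG channel is usable; after a continuous ExG outage longer
   than `gap_min` (default 5 min — the operationalization of "unstable for
   a sufficient amount of time") the SML substitutes; shorter outages stay
   UNSCORED. Offline, the distribution stream is decoded by Viterbi under a
   bigram transition model (additive smoothing 1e-4; UNSCORED epochs get
   uniform emissions), then a rule pass removes single-epoch stage islands.
   The island rule is the minimal "remove unlikely transitions" rule; the
   smoother always emits a complete hypnogram.

## The closed loop

The probability of being asleep (PoAs) is an EWMA of the instantaneous
sleep probability: `poas_t = a * poas_{t-1} + (1 - a) * (1 - p_W)` with
`a = 0.8`, initial value 0, carry-forward on UNSCORED epochs. PoAs is
defined behaviorally in the source literature (fast rise, plateau, rise to
> 0.8 at onset); the EWMA is the one-parameter form that reproduces that
shape, and its geometric convergence gives an exact closed form the tests
check to 1e-9.

Sleep onset (SOL) is the first epoch starting a run of `k = 3` consecutive
non-wake epochs; the persistence guard ignores single-epoch blips, and
`k = 1` recovers the literal first-transition rule. Audio follows a
three-component timeline (guided breathing voice until `t1`, relaxation
voice on `[t1, t2]`, background music throughout and alone after `t2`;
defaults t0 = 0, t1 = 8, t2 = 16 min, 30-s fades — structural values, since
only the shape of the timeline is specified in the source). All gains drop
to exactly 0 at SOL detection or at the 50-min cap.

Automatic content switching (ACS) fires when the trailing 5-min PoAs slope
is below 0.01/min within the first 20 min, with a 5-min dwell to prevent
thrashing. Content recommendation (ACR) is Thompson sampling over per-user,
per-content normal value posteriors with known observation variance: the
conjugate update `var' = 1/(1/var + 1/var_r)`,
`mu' = var' (mu/var + r/var_r)` is the simplest model in which the
posterior variance strictly decreases per observation, as described.
Rewards are the PoAs slope over each content's play interval, applied at
session end. The most-recently-used content is excluded from a draw only
when there *is* one (within-session switches); a fresh selection sequence
samples all contents — with a two-content catalog, unconditional exclusion
would force strict alternation and make convergence to a preferred content
impossible.

## The synthetic polysomnography simulator

The simulator is the package's study condition, not a tuning knob; its
defaults were fixed once:

* **Hypnogram**: truncated-normal initial wake run (mean 15, SD 5 min —
  the 10–20 min healthy-adult SOL range), then a first-order Markov chain
  with self-transitions near 0.85 favoring W→LS→DS and LS→REM paths. Real
  hypnograms motivate but do not specify dynamics; first-order Markov is
  the simplest structure the smoother's transition model can be honest
  about.
* **ExG**: per stage, amplitude-modulated oscillations over a 1/f
  background (10 µV) with a 2 µV white floor — W: 8–13 Hz alpha (40 µV) +
  blink deflections + broadband EMG (8 µV); LS: Poisson spindles (3/min,
  11–16 Hz, 30 µV) and K-complexes (1.5/min, biphasic, >= 75 µV
  peak-to-peak, standard sleep-medicine conventions); DS: 0.5–2 Hz delta
  (100 µV); REM: 4–8 Hz activity, rapid EOG deflections, minimal EMG.
  Forehead channels carry the EOG; bone-electrode sites see the cortical
  source only weakly (gain 0.25), which is what makes them meaningful
  references. A log-normal per-night scale (SD 0.2) emulates
  between-subject variability; without it, two training nights would
  suffice for any classifier and the pre-training experiment would be
  vacuous.
* **Vitals**: stage-conditional heart rate (W/LS/DS/REM = 68/62/57/66 bpm
  + per-subject offset + AR(1) wander) rendered as a phase-accumulator
  pulse train with ~2% beat-to-beat jitter; respiration
  (14.5/13/11.5/15 breaths/min) as a 0.02 g sinusoidal modulation on the
  gravity vector of the current posture; posture changes and movement
  bursts only during wake.
* **Artifacts**: per-channel contact-loss events (1/channel-hour) lasting
  1–40 epochs, as flatline, rail saturation (±500 µV), or high-amplitude
  motion noise. Events are aligned to the epoch grid so the ground-truth
  mask is unambiguous at the cell level.
* **Virtual sleeper**: a scalar sleep-propensity with drift
  `1/baseline_sol_min` plus a content-specific increment and diffusion
  noise; emissions switch from wake- to sleep-dominant across a threshold.
  Default content effects make the best content produce a ~15 min SOL from
  a 40-min baseline while an unhelpful one stays near baseline, mirroring
  the magnitude of SOL modulation reported for closed-loop acoustic
  stimulation; this heterogeneity is exactly what ACR exists to exploit.

## Numerical choices

* `bandpass()` is a frequency-domain filter with hard band edges: zero
  phase, length-preserving, and exactly idempotent (the band mask is
  binary). Narrow-band detector filters use zero-phase Butterworth
  (`signal::filtfilt`), where idempotence is not required.
* Welch PSD: 4-s Hann segments, 50% overlap, per-segment mean detrending;
  relative powers are normalized over the four bands, so they sum to 1 by
  construction.
* Viterbi decoding is done in log space with emission floors at 1e-12;
  ties are broken toward the lower stage index (measure-zero for
  continuous emissions). The decoder is verified against exhaustive path
  enumeration for streams up to 8 epochs.
* Respiratory-rate estimation block-averages the accelerometer to ~10 Hz
  first (respiration lives below 0.5 Hz) and interpolates the spectral
  peak parabolically, giving sub-bin resolution on a 2-epoch window.
* Consensus tie-breaking is fully deterministic: majority vote, then the
  technician with the highest mean pairwise agreement, then the lowest
  technician index.

## Problem sizes and what the benchmarks mean

The default benchmark pool is 50 simulated nights of 90 min each (40
training, 10 held out); the missing-segment experiment uses three 4-h
sessions with outages of 5–120 min at 10 trials per duration; the vitals
benchmark uses one 8-h night; the closed-loop comparison uses 20 paired
nights. These sizes were chosen as the smallest at which the evaluated
quantities are stable across seeds.

Passing benchmarks on this simulator shows that the pipeline is correct and
self-consistent: features separate the stages the generator encodes,
quality screening recovers exactly the corruption the generator injects,
the smoother is an exact MAP decoder, the bandit converges on the sleeper
model it is given. It does not show clinical performance: real dry-electrode
EEG has non-stationary artifacts, inter-subject morphology differences, and
stage phenomenology far richer than stage-conditional oscillation mixtures;
real sleep-onset dynamics are not a drift-diffusion scalar. Headline
accuracies on the synthetic benchmark are therefore upper bounds produced
by a generatively simple world, and the package reports them as such.

## Known limitations

* The classifier family is linear in the engineered features; it has no
  temporal context beyond the vitals rolling window (real-time causality is
  enforced instead).
* The spindle/slow-wave detectors use fixed conventional parameters; they
  are meant as feature extractors, not as clinical event scorers.
* No oxygen saturation, apnea, or periodic limb movement modeling; the
  simulator covers the modalities the scoring stack consumes, nothing
  more.
* EDF support is deliberately minimal (16-bit EDF, 30-s records, the ten
  device channels); EDF+ annotations are out of scope.
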