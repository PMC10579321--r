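# somnoloop

Sleep staging and closed-loop acoustic stimulation for headband-style
wearables, in R.

Consumer sleep-aid headbands record six dry-electrode ExG channels
(forehead `FH_L/FH_R`, over-the-ear `OTE_L/OTE_R`, behind-the-ear
`BE_L/BE_R`), photoplethysmography and 3-axis accelerometry, and must score
sleep **in real time** — one 30-s epoch at a time — to drive auditory
stimulation that helps the wearer fall asleep faster. somnoloop implements
that full computational stack for researchers and engineers who want a
tested, reproducible reference:

* **Scoring.** Per-epoch channel-quality screening; dynamic re-referencing
  with a contralateral-BE → ipsilateral-BE → raw fallback chain; spectral /
  hallmark-event features (Delta–Beta relative power, spindles, slow waves,
  EOG/EMG summaries); a primary ExG classifier and a secondary vitals
  classifier (heart rate from PPG peaks, respiratory rate and posture from
  the accelerometer) that substitutes during long ExG outages; offline
  smoothing by Viterbi decoding under a fitted stage-transition model
  $\hat{s}_{1:T} = \arg\max_{s_{1:T}} \pi(s_1)\prod_t P(s_{t-1},s_t)\, e_t(s_t)$
  followed by single-epoch-island removal, so every epoch ends up scored.
* **Closed loop.** A probability-of-being-asleep trace
  $\mathrm{PoAs}_t = \alpha\,\mathrm{PoAs}_{t-1} + (1-\alpha)(1 - p_W(t))$,
  sleep-onset detection with a persistence guard, a three-component audio
  timeline (guided breathing, relaxation voice, background music) that
  stops at onset or a 50-min cap, automatic content switching on a low
  PoAs slope, and Thompson-sampling content recommendation over conjugate
  normal preference posteriors rewarded by the PoAs slope.
* **Simulator.** A synthetic polysomnography generator (stage-dependent
  oscillations, vitals, posture, contact-loss artifacts, and closed-loop
  "virtual sleepers"), so the whole stack is testable end to end with no
  data download.

## Worked example

Simulate ten nights, train the two classifiers, and score a held-out night:

```r
library(somnoloop)

nights <- build_night_set(11, sim_config(duration_min = 90), seed_base = 101)
models <- train_on_nights(nights[1:10], seed = 1)

held_out <- nights[[11]]
dist <- predict_primary(models$pml, held_out$x, held_out$usable_n)
smoothed <- smooth_offline(dist, models$transitions)

agreement(smoothed, held_out$truth)[c("accuracy", "kappa")]
#> $accuracy
#> [1] 0.9944444
#>
#> $kappa
#> [1] 0.9924012
```

Accuracy here is per-epoch agreement with the generator's ground-truth
hypnogram over the 180 epochs of the held-out night, and kappa is its
chance-corrected counterpart — near-perfect because synthetic stages are
generatively clean (see the methods vignette for why this is an upper
bound, not a clinical claim).

Run one closed-loop night on a virtual sleeper:

```r
sleeper <- virtual_sleeper()     # 40-min baseline sleep-onset latency
post <- preference_posterior(names(sleeper$content_effect))
sess <- run_session(controller_config(), sleeper, names(sleeper$content_effect),
                    post, seed = 7)
c(sess$sol_min, sess$stop_reason)
#> [1] "16.5"         "sol_detected"
```

The controller detected sleep onset after 16.5 min and silenced the audio at
that epoch; `sess$log` holds the per-epoch PoAs, active content and
component gains, and `sess$posterior` the updated content preferences.

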