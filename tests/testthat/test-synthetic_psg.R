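test_that("hypnogram simulation is seeded, Markovian, and respects the wake run", {
  cfg <- sim_config(seed = 7, duration_min = 480)
  h1 <- simulate_hypnogram(cfg)
  h2 <- simulate_hypnogram(cfg)
  expect_identical(unclass(h1), unclass(h2))
  wr <- attr(h1, "wake_run_epochs")
  expect_true(wr >= 1)
  expect_true(all(unclass(h1)[seq_len(wr)] == "W"))

  # empirical proportions after the wake run track the chain's stationary
  # distribution (eigen-analysis oracle) within 5 percentage points
  stat <- stationary_distribution(cfg$transition_matrix)
  emp <- table(factor(unclass(h1)[-seq_len(wr)], levels = STAGES)) / (length(h1) - wr)
  expect_lt(max(abs(as.numeric(emp) - stat[STAGES])), 0.05)

  # an absorbing chain started in LS stays in LS (identity matrix warns about
  # the absorbing wake state but still generates)
  cfg_abs <- suppressWarnings(sim_config(seed = 1, duration_min = 30, transition_matrix = diag(4)))
  h_abs <- NULL
  expect_warning(h_abs <- simulate_hypnogram(cfg_abs), "absorbing")
  after <- unclass(h_abs)[-seq_len(attr(h_abs, "wake_run_epochs"))]
  expect_true(all(after == "LS"))
})

test_that("ExG synthesis has stage-conditional spectral signatures", {
  cfg <- sim_config(seed = 5, duration_min = 90)
  h <- simulate_hypnogram(cfg)
  rec <- synthesize_exg(h, cfg)
  expect_identical(synthesize_exg(h, cfg)$exg, rec$exg) # sample-for-sample determinism

  ns <- 6000
  dominant_band <- function(i) {
    x <- rec$exg[((i - 1) * ns + 1):(i * ns), "FH_L"]
    names(which.max(band_powers(x, 200)$relative))
  }
  stages <- unclass(h)
  ds <- which(stages == "DS")
  w <- which(stages == "W")
  expect_gte(length(ds), 20)
  expect_gte(length(w), 20)
  expect_identical(names(which.max(table(vapply(ds, dominant_band, "")))), "Delta")
  expect_identical(names(which.max(table(vapply(w, dominant_band, "")))), "Alpha")
})

test_that("deep sleep dominates Delta; silencing wake oscillations flattens the spectrum", {
  amp0 <- list(
    alpha = 0, spindle = 0, kcomplex = 0, delta = 80, theta = 0,
    blink = 0, rem_eog = 0, emg = c(W = 0, LS = 0, DS = 0, REM = 0)
  )
  # DS epoch with (almost) no background noise: Delta relative power maximal
  cfg <- sim_config(seed = 2, duration_min = 2, amplitudes = amp0,
                    noise_uv = 0.01, noise_white_uv = 0.01, initial_wake_run_min = c(mean = 0.5, sd = 0))
  rec <- synthesize_exg(hypnogram(rep("DS", 4)), cfg)
  rel <- band_powers(rec$exg[1:6000, "FH_L"], 200)$relative
  expect_identical(names(which.max(rel)), "Delta")
  expect_gt(rel[["Delta"]], 0.9)

  # W epoch with zero alpha and only a white floor: no band dominates the
  # per-Hz power density by more than 2x
  cfg_w <- sim_config(seed = 3, duration_min = 2, amplitudes = amp0,
                      noise_uv = 0, noise_white_uv = 2)
  rec_w <- synthesize_exg(hypnogram(rep("W", 4)), cfg_w)
  psd <- welch_psd(rec_w$exg[1:6000, "FH_L"], 200)
  dens <- vapply(seq_len(nrow(BANDS)), function(i) {
    sel <- psd$freq > BANDS$low[i] & psd$freq <= BANDS$high[i]
    mean(psd$psd[sel])
  }, 0)
  expect_lt(max(dens) / min(dens), 2)
})

test_that("vitals synthesis places spectral peaks at the configured rates", {
  # PPG fundamental at 1.00 Hz for 60 bpm
  p <- synth_ppg(60, duration_s = 120, rate = 64, jitter_rel = 0, noise = 0, seed = 1)
  sp <- Mod(fft(p - mean(p)))^2
  f <- (seq_along(sp) - 1) * 64 / length(sp)
  sel <- f > 0.3 & f < 3
  expect_lt(abs(f[sel][which.max(sp[sel])] - 1.0), 0.02)

  # RR fixed at 12 brpm: accelerometer band-power peak at 0.20 Hz
  cfg <- sim_config(
    seed = 4, duration_min = 10,
    rr_by_stage = list(mean = c(W = 12, LS = 12, DS = 12, REM = 12), sd = 0),
    rr_subject_sd = 0, posture_change_prob = 0, movement_burst_prob = 0
  )
  h <- hypnogram(rep("LS", 20))
  vit <- synthesize_vitals(h, cfg)
  ax <- vit$acc[, 1] - mean(vit$acc[, 1])
  sp <- Mod(fft(ax))^2
  f <- (seq_along(sp) - 1) * cfg$acc_rate / length(sp)
  sel <- f > 0.05 & f < 1
  expect_lt(abs(f[sel][which.max(sp[sel])] - 0.20), 0.01)

  # supine posture: mean gravity vector within 10 degrees of the reference
  m <- colMeans(vit$acc)
  ang <- acos(sum(m * c(0, 0, 1)) / sqrt(sum(m^2))) * 180 / pi
  expect_lt(ang, 10)
})

test_that("artifact injection masks exactly the corrupted cells and is a no-op at rate 0", {
  night <- small_night()
  cfg0 <- sim_config(seed = 1, duration_min = 30, artifact_rate_per_h = 0)
  clean <- inject_artifacts(night$recording, cfg0)
  expect_false(any(clean$mask))
  expect_identical(clean$recording$exg, night$recording$exg)

  # one forced 5-min flatline on FH_L: exactly 10 consecutive masked epochs
  ev <- data.frame(channel = "FH_L", start_epoch = 10L, n_epochs = 10L, kind = "flatline")
  inj <- inject_artifacts(night$recording, cfg0, events = ev)
  expect_equal(which(inj$mask[, "FH_L"]), 11:20)
  expect_false(any(inj$mask[, colnames(inj$mask) != "FH_L"]))
  seg <- inj$recording$exg[(10 * 6000 + 1):(20 * 6000), "FH_L"]
  expect_equal(stats::sd(seg), 0)
  # unmasked samples conserved exactly
  expect_identical(
    inj$recording$exg[-((10 * 6000 + 1):(20 * 6000)), "FH_L"],
    night$recording$exg[-((10 * 6000 + 1):(20 * 6000)), "FH_L"]
  )
  # seeded runs reproducible
  cfg4 <- sim_config(seed = 6, duration_min = 30, artifact_rate_per_h = 4)
  expect_identical(
    inject_artifacts(night$recording, cfg4)$mask,
    inject_artifacts(night$recording, cfg4)$mask
  )
})

test_that("virtual sleeper propensity follows a drift-diffusion with threshold emissions", {
  sl0 <- virtual_sleeper(content_effect = c(a = 0, b = 0), effect_sd = 0.05, relax_rate = 0)
  # driftless random walk: mean end point of 1000 seeded runs within 2 SE of 0
  set.seed(11)
  ends <- replicate(1000, {
    st <- list(propensity = 0)
    for (i in 1:20) st <- simulate_closed_loop_step(sl0, "a", st)$state
    st$propensity
  })
  se <- sd(ends) / sqrt(length(ends))
  expect_lt(abs(mean(ends)), 2 * se + 1e-9)

  # large positive drift: sustained sleep-dominant emissions within 50 min in
  # every one of 100 seeded runs
  sl1 <- virtual_sleeper(content_effect = c(a = 0.05), effect_sd = 0.01, relax_rate = 0.05)
  set.seed(12)
  onsets <- replicate(100, {
    st <- list(propensity = 0)
    stages <- character(100)
    for (i in 1:100) {
      step <- simulate_closed_loop_step(sl1, "a", st)
      st <- step$state
      stages[i] <- STAGES[which.max(step$dist)]
    }
    sol <- detect_sol(stages)
    if (is.null(sol)) Inf else sol$minutes
  })
  expect_true(all(onsets <= 50))

  # unknown content errors; identical seeds give identical trajectories
  expect_error(simulate_closed_loop_step(sl1, "nope", list(propensity = 0)),
               class = "unknown_content")
  tr <- function() {
    set.seed(3)
    st <- list(propensity = 0)
    vapply(1:30, function(i) {
      st <<- simulate_closed_loop_step(sl1, "a", st)$state
      st$propensity
    }, 0)
  }
  expect_identical(tr(), tr())

  # emissions are wake-dominant below threshold, sleep-dominant above
  d_low <- simulate_closed_loop_step(virtual_sleeper(effect_sd = 0), NULL,
                                     list(propensity = 0))$dist
  d_high <- simulate_closed_loop_step(virtual_sleeper(effect_sd = 0), NULL,
                                      list(propensity = 2))$dist
  expect_gt(d_low[["W"]], 0.5)
  expect_lt(d_high[["W"]], 0.5)
  expect_equal(sum(d_low), 1)
  expect_equal(sum(d_high), 1)
})
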