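#' Simulator configuration
#'
#' All knobs of the synthetic polysomnography generator. The defaults encode
#' the study conditions the pipeline assumes: a first-order Markov hypnogram
#' with self-transitions near 0.85, an initial wake run drawn from a
#' truncated normal sleep-onset-latency prior (10-20 min for healthy adults,
#' mean 15 min here), stage-dependent oscillation amplitudes at conventional
#' scalp values, stage-dependent heart and respiratory rates, posture changes
#' restricted to wake, and contact-loss artifacts at a rate of one event per
#' channel-hour.
#'
#' @param seed integer; fixes every random draw of every generator.
#' @param duration_min total recording duration in minutes.
#' @param exg_rate,ppg_rate,acc_rate sampling rates (Hz).
#' @param transition_matrix 4x4 per-epoch stage transition matrix
#'   (rows/cols in `STAGES` order); rows must sum to 1.
#' @param initial_wake_run_min mean/sd (minutes) of the initial wake run.
#' @param amplitudes named list of per-stage oscillation amplitudes (uV):
#'   `alpha`, `spindle`, `kcomplex`, `delta`, `theta`, `blink`, `rem_eog`,
#'   and the per-stage EMG noise SDs `emg` (named by stage).
#' @param noise_uv SD of the 1/f background noise (uV).
#' @param noise_white_uv SD of the broadband white noise floor (uV).
#' @param spindle_rate_per_min,kcomplex_rate_per_min Poisson event rates in LS.
#' @param blink_rate_per_min blink rate in W; `rem_eog_rate_per_min` rapid
#'   eye-movement deflection rate in REM.
#' @param artifact_rate_per_h expected contact-loss events per channel-hour.
#' @param clip_uv amplifier rail (uV); signals and artifacts saturate here.
#' @param hr_by_stage,rr_by_stage lists with named `mean` vectors (per stage)
#'   and scalar `sd` (within-night wander innovation).
#' @param hr_subject_sd,rr_subject_sd between-subject SD of the night baseline.
#' @param posture_change_prob probability of a posture change per wake epoch.
#' @param movement_burst_prob probability of a movement burst per wake epoch.
#' @param subject_sd log-normal SD of per-night global amplitude/noise scale
#'   (between-subject signal variability).
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(
    seed = 1, duration_min = 480,
    exg_rate = 200, ppg_rate = 64, acc_rate = 50,
    transition_matrix = default_transitions(),
    initial_wake_run_min = c(mean = 15, sd = 5),
    amplitudes = list(
      alpha = 40, spindle = 30, kcomplex = 60, delta = 100, theta = 25,
      blink = 60, rem_eog = 50,
      emg = c(W = 8, LS = 3, DS = 2, REM = 1)
    ),
    noise_uv = 10, noise_white_uv = 2,
    spindle_rate_per_min = 3, kcomplex_rate_per_min = 1.5,
    blink_rate_per_min = 4, rem_eog_rate_per_min = 10,
    artifact_rate_per_h = 1, clip_uv = 500,
    hr_by_stage = list(mean = c(W = 68, LS = 62, DS = 57, REM = 66), sd = 1),
    rr_by_stage = list(mean = c(W = 14.5, LS = 13, DS = 11.5, REM = 15), sd = 0.3),
    hr_subject_sd = 4, rr_subject_sd = 1,
    posture_change_prob = 0.2, movement_burst_prob = 0.3,
    subject_sd = 0.2) {
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(4, 4))) sl_error("transition_matrix must be 4x4", "invalid_config")
  if (any(abs(rowSums(tm) - 1) > 1e-8) || any(tm < 0)) {
    sl_error("transition_matrix rows must be probabilities summing to 1", "invalid_config")
  }
  dimnames(tm) <- list(STAGES, STAGES)
  cfg <- as.list(environment())
  cfg$transition_matrix <- tm
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_transitions <- function() {
  m <- rbind(
    W   = c(0.850, 0.140, 0.005, 0.005),
    LS  = c(0.030, 0.820, 0.100, 0.050),
    DS  = c(0.005, 0.115, 0.870, 0.010),
    REM = c(0.040, 0.110, 0.005, 0.845)
  )
  colnames(m) <- STAGES
  m
}

#' Stationary distribution of a stage transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' a probability vector.
#'
#' @param tm 4x4 row-stochastic matrix.
#' @return named numeric vector over [STAGES].
#' @export
stationary_distribution <- function(tm) {
  e <- eigen(t(tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stats::setNames(v / sum(v), rownames(tm))
}

#' Simulate a ground-truth hypnogram
#'
#' An initial wake run (truncated-normal sleep-onset latency, minimum one
#' epoch) followed by a first-order Markov chain over the four stages,
#' entering sleep through LS. Deterministic under `config$seed`.
#'
#' @param config a [sim_config].
#' @return a [hypnogram] with attribute `wake_run_epochs`.
#' @export
simulate_hypnogram <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tm <- config$transition_matrix
  if (tm["W", "W"] >= 1 - 1e-12) {
    warning("transition matrix has absorbing wake: hypnogram will never leave W")
  }
  n_ep <- as.integer(config$duration_min * 2)
  with_seed(config$seed + 11L, {
    sol_min <- max(0.5, stats::rnorm(1, config$initial_wake_run_min[["mean"]],
                                     config$initial_wake_run_min[["sd"]]))
    wake_run <- max(1L, as.integer(round(sol_min * 2)))
    wake_run <- min(wake_run, n_ep)
    stages <- character(n_ep)
    stages[seq_len(wake_run)] <- "W"
    if (wake_run < n_ep) {
      s <- "LS"
      for (i in (wake_run + 1):n_ep) {
        stages[i] <- s
        s <- sample(STAGES, 1, prob = tm[s, ])
      }
    }
    h <- hypnogram(stages)
    attr(h, "wake_run_epochs") <- wake_run
    h
  })
}

# raised-cosine windowed oscillatory burst added in place
add_burst <- function(seg, fs, t0, dur, freq, amp, shape = c("sine", "mono")) {
  shape <- match.arg(shape)
  i0 <- floor(t0 * fs) + 1L
  i1 <- min(length(seg), i0 + ceiling(dur * fs) - 1L)
  if (i1 <= i0) return(seg)
  idx <- i0:i1
  u <- seq(0, 1, length.out = length(idx))
  env <- 0.5 * (1 - cos(2 * pi * u))
  if (shape == "sine") {
    seg[idx] <- seg[idx] + amp * env * sin(2 * pi * freq * (idx - i0) / fs + stats::runif(1, 0, 2 * pi))
  } else {
    # monophasic deflection (blink-like)
    seg[idx] <- seg[idx] + amp * env
  }
  seg
}

#' Synthesize six-channel ExG from a hypnogram
#'
#' Per epoch, a stage-conditional mixture over a 1/f background: wake carries
#' amplitude-modulated 8-13 Hz alpha, blink-like low-frequency EOG
#' deflections on the forehead channels and broadband EMG; light sleep
#' carries 11-16 Hz spindle bursts at a Poisson rate plus occasional
#' K-complex biphasic transients; deep sleep carries high-amplitude 0.5-2 Hz
#' delta; REM carries 4-8 Hz mixed activity, rapid large EOG deflections and
#' minimal EMG. Channels share the cortical source through per-night gain
#' asymmetries and receive independent noise. Deterministic under
#' `config$seed`.
#'
#' @param hyp a [hypnogram].
#' @param config a [sim_config].
#' @return a [recording] (ExG only).
#' @export
synthesize_exg <- function(hyp, config) {
  stopifnot(is_hypnogram(hyp), inherits(config, "sim_config"))
  fs <- config$exg_rate
  ns <- as.integer(fs * 30)
  n_ep <- length(hyp)
  N <- n_ep * ns
  A <- config$amplitudes
  with_seed(config$seed + 22L, {
    amp_scale <- exp(stats::rnorm(1, 0, config$subject_sd))
    noise_scale <- exp(stats::rnorm(1, 0, config$subject_sd))
    alpha_shift <- stats::rnorm(1, 0, 0.5)
    # scalp topography: forehead sees the cortical source fully, over-the-ear
    # partially, and the bone-electrode sites only weakly (which is what makes
    # them usable as references)
    base_gain <- c(FH_L = 1, FH_R = 1, OTE_L = 0.85, OTE_R = 0.85, BE_L = 0.25, BE_R = 0.25)
    gains <- pmax(0.05, base_gain * stats::rnorm(6, 1, 0.05))
    eog_gain <- c(FH_L = 1, FH_R = 1, OTE_L = 0.3, OTE_R = 0.3, BE_L = 0.1, BE_R = 0.1)

    cortical <- numeric(N)
    eog <- numeric(N)
    emg_sd <- numeric(n_ep)
    t_ep <- (seq_len(ns) - 1) / fs

    for (i in seq_len(n_ep)) {
      st <- hyp[[i]]
      seg <- numeric(ns)
      eseg <- numeric(ns)
      if (st == "W") {
        f <- stats::runif(1, 8.5, 12.5) + alpha_shift
        env <- 0.65 + 0.35 * sin(2 * pi * 0.2 * t_ep + stats::runif(1, 0, 2 * pi))
        seg <- seg + A$alpha * amp_scale * env * sin(2 * pi * f * t_ep + stats::runif(1, 0, 2 * pi))
        for (k in seq_len(stats::rpois(1, config$blink_rate_per_min * 0.5))) {
          eseg <- add_burst(eseg, fs, stats::runif(1, 0, 29.5), stats::runif(1, 0.2, 0.4),
                            0, A$blink * amp_scale, shape = "mono")
        }
      } else if (st == "LS") {
        seg <- seg + 0.4 * A$theta * amp_scale *
          sin(2 * pi * stats::runif(1, 4, 7) * t_ep + stats::runif(1, 0, 2 * pi))
        seg <- seg + 0.25 * A$delta * amp_scale *
          sin(2 * pi * stats::runif(1, 0.7, 1.8) * t_ep + stats::runif(1, 0, 2 * pi))
        for (k in seq_len(stats::rpois(1, config$spindle_rate_per_min * 0.5))) {
          seg <- add_burst(seg, fs, stats::runif(1, 0, 28), stats::runif(1, 0.5, 2),
                           stats::runif(1, 11, 16), A$spindle * amp_scale)
        }
        for (k in seq_len(stats::rpois(1, config$kcomplex_rate_per_min * 0.5))) {
          d <- stats::runif(1, 0.5, 1.5)
          t0 <- stats::runif(1, 0, 28)
          i0 <- floor(t0 * fs) + 1L
          i1 <- min(ns, i0 + ceiling(d * fs) - 1L)
          if (i1 > i0) {
            u <- seq(0, 1, length.out = i1 - i0 + 1)
            # single-cycle biphasic transient: sharp trough then rebound
            seg[i0:i1] <- seg[i0:i1] - A$kcomplex * amp_scale * sin(2 * pi * u) * sin(pi * u)^0.5
          }
        }
      } else if (st == "DS") {
        f <- stats::runif(1, 0.6, 1.8)
        env <- 0.75 + 0.25 * sin(2 * pi * 0.1 * t_ep + stats::runif(1, 0, 2 * pi))
        seg <- seg + A$delta * amp_scale * env * sin(2 * pi * f * t_ep + stats::runif(1, 0, 2 * pi))
        seg <- seg + 0.2 * A$theta * amp_scale *
          sin(2 * pi * stats::runif(1, 4, 6) * t_ep + stats::runif(1, 0, 2 * pi))
      } else { # REM
        f <- stats::runif(1, 4.5, 7.5)
        env <- 0.7 + 0.3 * sin(2 * pi * 0.15 * t_ep + stats::runif(1, 0, 2 * pi))
        seg <- seg + A$theta * amp_scale * env * sin(2 * pi * f * t_ep + stats::runif(1, 0, 2 * pi))
        for (k in seq_len(stats::rpois(1, config$rem_eog_rate_per_min * 0.5))) {
          d <- stats::runif(1, 0.2, 0.4)
          t0 <- stats::runif(1, 0, 29)
          i0 <- floor(t0 * fs) + 1L
          i1 <- min(ns, i0 + ceiling(d * fs) - 1L)
          if (i1 > i0) {
            u <- seq(0, 1, length.out = i1 - i0 + 1)
            eseg[i0:i1] <- eseg[i0:i1] +
              A$rem_eog * amp_scale * sin(2 * pi * u) * sample(c(-1, 1), 1)
          }
        }
      }
      rng <- ((i - 1) * ns + 1):(i * ns)
      cortical[rng] <- seg
      eog[rng] <- eseg
      emg_sd[i] <- A$emg[[st]] * amp_scale
    }

    # white floor and EMG noise share one Gaussian draw per channel
    broadband_sd <- rep(sqrt(config$noise_white_uv^2 + emg_sd^2), each = ns)
    exg <- matrix(0, N, 6, dimnames = list(NULL, EXG_CHANNELS))
    for (c in seq_len(6)) {
      ch <- EXG_CHANNELS[c]
      exg[, c] <- cortical * gains[c] + eog * eog_gain[[ch]] +
        pink_noise(N, fs) * config$noise_uv * noise_scale +
        stats::rnorm(N, 0, 1) * broadband_sd
    }
    exg <- pmin(pmax(exg, -config$clip_uv), config$clip_uv)
    recording(exg = exg, exg_rate = fs, ppg = NULL, acc = NULL)
  })
}

# canonical gravity orientations (device frame, units of g)
POSTURE_REFS <- list(
  supine  = c(0, 0, 1),
  prone   = c(0, 0, -1),
  left    = c(0, -1, 0),
  right   = c(0, 1, 0),
  upright = c(1, 0, 0)
)

# phase-accumulator PPG pulse train; hr_hz per output sample
gen_ppg <- function(hr_hz, rate, jitter_rel = 0.02, noise = 0.02) {
  n <- length(hr_hz)
  # low-passed frequency jitter => beat-to-beat interval jitter
  j <- if (jitter_rel > 0) {
    a <- exp(-2 * pi * 1.5 / rate)
    z <- as.numeric(stats::filter(stats::rnorm(n), a, method = "recursive")) * (1 - a)
    jitter_rel * z / max(stats::sd(z), 1e-12)
  } else {
    numeric(n)
  }
  phase <- 2 * pi * cumsum(hr_hz * (1 + j)) / rate
  pm <- phase %% (2 * pi)
  w <- exp(-(pm - 1.0)^2 / (2 * 0.32^2)) + 0.35 * exp(-(pm - 2.8)^2 / (2 * 0.65^2))
  tt <- (seq_len(n) - 1) / rate
  w + 0.2 * sin(2 * pi * 0.08 * tt) + stats::rnorm(n, 0, noise)
}

#' Synthesize a PPG pulse train at a known heart rate
#'
#' Convenience wrapper around the simulator's pulse model, used for
#' controlled heart-rate recovery experiments.
#'
#' @param hr_bpm heart rate in beats per minute (scalar or per-sample vector).
#' @param duration_s duration in seconds (ignored when `hr_bpm` is a vector).
#' @param rate sampling rate (Hz).
#' @param jitter_rel relative beat-to-beat interval jitter SD (0.02 = 2\%,
#'   about 20 ms at 60 bpm).
#' @param noise additive white noise SD (signal units).
#' @param seed RNG seed.
#' @return numeric PPG samples.
#' @export
synth_ppg <- function(hr_bpm, duration_s = 60, rate = 64, jitter_rel = 0.02,
                      noise = 0.02, seed = 1) {
  hr_hz <- if (length(hr_bpm) > 1) hr_bpm / 60 else rep(hr_bpm / 60, round(duration_s * rate))
  with_seed(seed, gen_ppg(hr_hz, rate, jitter_rel, noise))
}

#' Synthesize PPG, accelerometer and per-epoch vitals ground truth
#'
#' The PPG is a periodic pulse waveform at a stage-conditional heart rate
#' with beat-to-beat jitter; the accelerometer carries the gravity vector of
#' the current posture, a sinusoidal respiratory modulation at a
#' stage-conditional rate, and movement bursts during wake. Posture changes
#' only during wake epochs. Deterministic under `config$seed`.
#'
#' @param hyp a [hypnogram].
#' @param config a [sim_config].
#' @return list with `ppg`, `acc` (n x 3), `ppg_rate`, `acc_rate` and
#'   `truth`: a data frame with per-epoch `stage`, `hr_bpm`, `rr_brpm`,
#'   `posture` and `movement` flag.
#' @export
synthesize_vitals <- function(hyp, config) {
  stopifnot(is_hypnogram(hyp), inherits(config, "sim_config"))
  n_ep <- length(hyp)
  stages <- unclass(hyp)
  with_seed(config$seed + 33L, {
    hr_subj <- stats::rnorm(1, 0, config$hr_subject_sd)
    rr_subj <- stats::rnorm(1, 0, config$rr_subject_sd)
    ar1 <- function(n, sd) {
      as.numeric(stats::filter(stats::rnorm(n, 0, sd), 0.9, method = "recursive"))
    }
    hr_ep <- config$hr_by_stage$mean[stages] + hr_subj + ar1(n_ep, config$hr_by_stage$sd)
    rr_ep <- config$rr_by_stage$mean[stages] + rr_subj + ar1(n_ep, config$rr_by_stage$sd)
    hr_ep <- pmax(35, hr_ep); rr_ep <- pmax(6, rr_ep)

    # posture path: changes only in wake
    posture <- character(n_ep)
    posture[1] <- "supine"
    for (i in seq_len(n_ep)[-1]) {
      posture[i] <- posture[i - 1]
      if (stages[i] == "W" && stats::runif(1) < config$posture_change_prob) {
        posture[i] <- sample(setdiff(names(POSTURE_REFS), posture[i - 1]), 1)
      }
    }

    fs_p <- config$ppg_rate
    ppg <- gen_ppg(rep(hr_ep / 60, each = fs_p * 30), fs_p)

    fs_a <- config$acc_rate
    na <- as.integer(fs_a * 30)
    Na <- n_ep * na
    grav <- do.call(rbind, POSTURE_REFS[posture])
    acc <- grav[rep(seq_len(n_ep), each = na), , drop = FALSE]
    resp_dir <- c(0.8, 0.6, 0) / sqrt(0.8^2 + 0.6^2)
    resp_phase <- 2 * pi * cumsum(rep(rr_ep / 60, each = na)) / fs_a
    resp <- 0.02 * sin(resp_phase)
    acc <- acc + outer(resp, resp_dir)
    movement <- logical(n_ep)
    for (i in seq_len(n_ep)) {
      if (stages[i] == "W" && stats::runif(1) < config$movement_burst_prob) {
        movement[i] <- TRUE
        dur <- stats::runif(1, 2, 10)
        off <- stats::runif(1, 0, 30 - dur)
        i0 <- (i - 1) * na + floor(off * fs_a) + 1L
        i1 <- min(Na, i0 + ceiling(dur * fs_a))
        acc[i0:i1, ] <- acc[i0:i1, ] + matrix(stats::rnorm(3 * (i1 - i0 + 1), 0, 0.3), ncol = 3)
      }
    }
    acc <- acc + matrix(stats::rnorm(3 * Na, 0, 0.005), ncol = 3)
    colnames(acc) <- c("ACC_X", "ACC_Y", "ACC_Z")

    list(
      ppg = ppg, ppg_rate = fs_p, acc = acc, acc_rate = fs_a,
      truth = data.frame(
        epoch = seq_len(n_ep) - 1L, stage = stages,
        hr_bpm = unname(hr_ep), rr_brpm = unname(rr_ep),
        posture = posture, movement = movement
      )
    )
  })
}

#' Inject contact-loss artifacts into a recording
#'
#' Per-channel contact-loss events at `config$artifact_rate_per_h`, each
#' replacing the affected samples with a flatline, rail saturation, or
#' high-amplitude motion noise. Events are aligned to the 30-s epoch grid and
#' last 1-40 epochs (30 s to 20 min). The input recording is not modified.
#'
#' @param rec a [recording].
#' @param config a [sim_config].
#' @param events optional data frame (`channel`, `start_epoch` 0-based,
#'   `n_epochs`, `kind`) to inject deterministically instead of sampling.
#' @return list with `recording` (a modified copy), `mask` (epoch x channel
#'   logical matrix, `TRUE` = corrupted) and `events`.
#' @export
inject_artifacts <- function(rec, config, events = NULL) {
  stopifnot(inherits(rec, "recording"))
  ns <- as.integer(rec$exg_rate * 30)
  n_ep <- floor(nrow(rec$exg) / ns)
  N <- n_ep * ns
  kinds <- c("flatline", "saturation", "motion")
  if (is.null(events)) {
    events <- with_seed(config$seed + 44L, {
      out <- list()
      hours <- n_ep / 120
      for (ch in EXG_CHANNELS) {
        n_ev <- stats::rpois(1, config$artifact_rate_per_h * hours)
        if (n_ev > 0) {
          out[[ch]] <- data.frame(
            channel = ch,
            start_epoch = sample.int(n_ep, n_ev, replace = TRUE) - 1L,
            n_epochs = sample.int(40, n_ev, replace = TRUE),
            kind = sample(kinds, n_ev, replace = TRUE)
          )
        }
      }
      if (length(out)) do.call(rbind, out) else
        data.frame(channel = character(), start_epoch = integer(),
                   n_epochs = integer(), kind = character())
    })
  }
  exg <- rec$exg
  mask <- matrix(FALSE, n_ep, 6, dimnames = list(NULL, EXG_CHANNELS))
  if (nrow(events)) {
    corrupt <- with_seed(config$seed + 45L, {
      lapply(seq_len(nrow(events)), function(k) {
        e <- events[k, ]
        e0 <- e$start_epoch
        e1 <- min(n_ep - 1L, e0 + e$n_epochs - 1L)
        idx <- (e0 * ns + 1):((e1 + 1) * ns)
        x <- switch(as.character(e$kind),
          flatline = rep(exg[idx[1], e$channel], length(idx)),
          saturation = config$clip_uv *
            sign(sin(2 * pi * 0.25 * (seq_along(idx) - 1) / rec$exg_rate) + 0.5),
          motion = pmin(pmax(stats::rnorm(length(idx), 0, 300), -config$clip_uv),
                        config$clip_uv)
        )
        list(idx = idx, channel = e$channel, x = x, epochs = e0:e1)
      })
    })
    for (cr in corrupt) {
      exg[cr$idx, cr$channel] <- cr$x
      mask[cr$epochs + 1L, cr$channel] <- TRUE
    }
  }
  out <- rec
  out$exg <- exg
  list(recording = out, mask = mask, events = events)
}

## ---------------------------------------------------------------------------
## Virtual sleeper (closed-loop testbed)

#' Construct a virtual sleeper
#'
#' A latent "sleep propensity" scalar that drifts upward at a relaxation rate
#' plus an audio-content-specific increment, with diffusion noise; sleep
#' emissions switch from wake-dominant to sleep-dominant as the propensity
#' crosses 1. Mean sleep-onset latency with no audio is approximately
#' `baseline_sol_min`.
#'
#' @param baseline_sol_min baseline sleep-onset latency (minutes).
#' @param content_effect named numeric: per-minute drift increment of each
#'   audio content while it plays.
#' @param effect_sd diffusion SD (per sqrt-minute).
#' @param relax_rate drift per minute with no audio; defaults to
#'   `1 / baseline_sol_min`.
#' @return an object of class `"virtual_sleeper"`.
#' @export
virtual_sleeper <- function(baseline_sol_min = 40,
                            content_effect = c(calm = 0.04, rain = -0.005, piano = 0.01),
                            effect_sd = 0.03, relax_rate = NULL) {
  if (effect_sd < 0) sl_error("effect_sd must be >= 0", "invalid_config")
  structure(
    list(
      baseline_sol_min = baseline_sol_min,
      content_effect = content_effect,
      effect_sd = effect_sd,
      relax_rate = if (is.null(relax_rate)) 1 / baseline_sol_min else relax_rate
    ),
    class = "virtual_sleeper"
  )
}

#' Advance the virtual sleeper by one epoch
#'
#' Drift-diffusion update of the latent propensity, followed by a threshold
#' emission: the emitted stage distribution is wake-dominant below the onset
#' threshold and sleep-dominant above it, so downstream probability-of-being-
#' asleep traces show the characteristic fast rise, plateau, and final rise
#' above 0.8. Uses the current RNG stream (seed at the session level).
#'
#' @param sleeper a [virtual_sleeper].
#' @param content active audio content id, or `NULL` for silence.
#' @param state list with `propensity`; use `list(propensity = 0)` to start.
#' @param dt_min epoch duration in minutes (0.5).
#' @return list with updated `state` and `dist`, a named stage-probability
#'   vector over [STAGES].
#' @export
simulate_closed_loop_step <- function(sleeper, content, state, dt_min = 0.5) {
  stopifnot(inherits(sleeper, "virtual_sleeper"))
  drift <- sleeper$relax_rate
  if (!is.null(content)) {
    if (!content %in% names(sleeper$content_effect)) {
      sl_error(paste0("unknown audio content: ", content), "unknown_content")
    }
    drift <- drift + sleeper$content_effect[[content]]
  }
  p <- state$propensity + drift * dt_min +
    stats::rnorm(1, 0, sleeper$effect_sd * sqrt(dt_min))
  p_sleep <- 0.12 + 0.8 * stats::plogis(10 * (p - 1))
  dist <- c(W = 1 - p_sleep, LS = 0.8 * p_sleep, DS = 0.1 * p_sleep, REM = 0.1 * p_sleep)
  list(state = list(propensity = p), dist = dist)
}
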