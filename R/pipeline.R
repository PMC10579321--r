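#' Per-epoch ExG features for a whole recording
#'
#' The full primary feature pipeline: channel quality assessment, per-epoch
#' channel selection, re-referencing under the chosen scheme, night-level
#' hallmark-event detection on the mean derived trace, and the per-epoch
#' feature vector of [exg_feature_vector].
#'
#' @param rec a [recording].
#' @param thresholds a [quality_thresholds] list.
#' @param scheme re-referencing scheme (see [rereference]).
#' @return list with `features` (epochs x `EXG_FEATURE_NAMES` matrix; `NA`
#'   rows for ExG-unscorable epochs), `usable_n` (usable channels per epoch),
#'   `grid` (the quality grid).
#' @export
night_features <- function(rec, thresholds = quality_thresholds(),
                           scheme = "dynamic") {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$exg_rate
  ns <- as.integer(fs * 30)
  n_ep <- floor(nrow(rec$exg) / ns)
  grid <- assess_recording(rec, thresholds)
  usable_by_epoch <- split(grid$channel[grid$scorable], grid$epoch[grid$scorable])

  derived <- vector("list", n_ep)
  mean_trace <- numeric(n_ep * ns)
  usable_n <- integer(n_ep)
  for (i in seq_len(n_ep)) {
    usable <- usable_by_epoch[[as.character(i - 1L)]]
    if (is.null(usable)) usable <- character(0)
    idx <- ((i - 1) * ns + 1):(i * ns)
    d <- rereference(rec$exg[idx, , drop = FALSE], usable, scheme)
    derived[[i]] <- d
    usable_n[i] <- length(usable)
    if (ncol(d) > 0) mean_trace[idx] <- rowMeans(d)
  }

  sp <- detect_spindles(mean_trace, fs)
  sw <- detect_slow_waves(mean_trace, fs)
  sp_ep <- floor(sp$t_start_s / 30)
  sw_ep <- floor(sw$t_start_s / 30)

  x <- matrix(NA_real_, n_ep, length(EXG_FEATURE_NAMES),
              dimnames = list(NULL, EXG_FEATURE_NAMES))
  for (i in seq_len(n_ep)) {
    if (ncol(derived[[i]]) == 0) next
    ev <- list(
      spindles = sp[sp_ep == i - 1L, , drop = FALSE],
      slow_waves = sw[sw_ep == i - 1L, , drop = FALSE]
    )
    x[i, ] <- exg_feature_vector(derived[[i]], fs, events = ev)
  }
  list(features = x, usable_n = usable_n, grid = grid)
}

SEC_FEATURE_NAMES <- c(
  "hr", "rr", "log_motion",
  "posture_supine", "posture_prone", "posture_left", "posture_right", "posture_upright",
  "hr_roll_mean", "hr_roll_sd", "rr_roll_mean", "rr_roll_sd", "motion_roll_mean"
)

roll_trailing <- function(x, k, fun = mean) {
  n <- length(x)
  vapply(seq_len(n), function(i) fun(x[max(1, i - k + 1):i]), 0)
}

#' Vitals context features for the secondary classifier
#'
#' Per-epoch heart rate, respiratory rate, motion and posture, plus trailing
#' context-window summaries (default 10 epochs). Invalid HR/RR values are
#' carried forward from the last valid epoch; an epoch whose whole context
#' window contains no valid HR and no valid RR is marked unusable.
#'
#' @param vitals output of [vitals_series].
#' @param w_ctx context window length in epochs.
#' @return list with `features` (epochs x `SEC_FEATURE_NAMES`) and `valid_n`
#'   (number of valid HR/RR observations in each epoch's window; 0 marks the
#'   epoch unusable for the secondary classifier).
#' @export
secondary_features <- function(vitals, w_ctx = 10) {
  n <- nrow(vitals)
  locf <- function(x, valid) {
    x[!valid] <- NA
    filled <- x
    last <- NA_real_
    for (i in seq_len(n)) {
      if (!is.na(filled[i])) last <- filled[i] else filled[i] <- last
    }
    filled[is.na(filled)] <- stats::median(x, na.rm = TRUE)
    filled[is.na(filled)] <- 0
    filled
  }
  hr <- locf(vitals$hr_bpm, vitals$hr_valid)
  rr <- locf(vitals$rr_brpm, vitals$rr_valid)
  motion <- vitals$motion_rms
  motion[is.na(motion)] <- 0
  post <- vapply(names(POSTURE_REFS), function(p) {
    as.numeric(!is.na(vitals$posture) & vitals$posture == p)
  }, numeric(n))
  x <- cbind(
    hr = hr, rr = rr, log_motion = log1p(motion),
    posture_supine = post[, "supine"], posture_prone = post[, "prone"],
    posture_left = post[, "left"], posture_right = post[, "right"],
    posture_upright = post[, "upright"],
    hr_roll_mean = roll_trailing(hr, w_ctx), hr_roll_sd = roll_trailing(hr, w_ctx, stats::sd),
    rr_roll_mean = roll_trailing(rr, w_ctx), rr_roll_sd = roll_trailing(rr, w_ctx, stats::sd),
    motion_roll_mean = roll_trailing(log1p(motion), w_ctx)
  )
  x[is.na(x)] <- 0
  colnames(x) <- SEC_FEATURE_NAMES
  valid_any <- as.numeric(vitals$hr_valid) + as.numeric(vitals$rr_valid)
  valid_n <- as.integer(round(roll_trailing(valid_any, w_ctx, sum)))
  list(features = x, valid_n = valid_n)
}

#' Simulate one complete synthetic night
#'
#' Hypnogram, six-channel ExG, PPG/accelerometer vitals and (optionally)
#' contact-loss artifacts, assembled into one [recording] with the
#' generator's ground truth attached.
#'
#' @param config a [sim_config].
#' @param with_artifacts inject contact-loss artifacts?
#' @return list with `recording`, `hypnogram`, `truth` (per-epoch vitals
#'   ground truth), and when artifacts are injected `mask` and `events`.
#' @export
simulate_night <- function(config, with_artifacts = FALSE) {
  hyp <- simulate_hypnogram(config)
  rec <- synthesize_exg(hyp, config)
  vit <- synthesize_vitals(hyp, config)
  rec <- recording(
    exg = rec$exg, exg_rate = rec$exg_rate,
    ppg = vit$ppg, ppg_rate = vit$ppg_rate,
    acc = vit$acc, acc_rate = vit$acc_rate
  )
  out <- list(recording = rec, hypnogram = hyp, truth = vit$truth)
  if (with_artifacts) {
    inj <- inject_artifacts(rec, config)
    out$recording <- inj$recording
    out$mask <- inj$mask
    out$events <- inj$events
  }
  out
}

#' Score one night end to end
#'
#' Quality assessment, feature extraction, primary and secondary prediction,
#' real-time fusion and offline smoothing, using trained models.
#'
#' @param rec a [recording].
#' @param pml,sml trained primary / secondary `"staging_model"`s (`sml` may
#'   be `NULL`).
#' @param transitions a [fit_transitions] model.
#' @param gap_min fusion gap (minutes), see [fuse_realtime].
#' @return list with `realtime` (fused output of [fuse_realtime]),
#'   `smoothed` (a [hypnogram]), `primary`, `secondary` distribution streams.
#' @export
score_night <- function(rec, pml, sml = NULL, transitions, gap_min = 5) {
  fx <- night_features(rec)
  primary <- predict_primary(pml, fx$features, fx$usable_n)
  n <- nrow(primary)
  secondary <- matrix(NA_real_, n, 4, dimnames = list(NULL, STAGES))
  if (!is.null(sml) && !is.null(rec$ppg) && !is.null(rec$acc)) {
    vs <- vitals_series(rec)
    sx <- secondary_features(vs)
    m <- min(n, nrow(sx$features))
    secondary[seq_len(m), ] <- predict_secondary(
      sml, sx$features[seq_len(m), , drop = FALSE], sx$valid_n[seq_len(m)]
    )
  }
  rt <- fuse_realtime(primary, secondary, gap_min)
  sm <- smooth_offline(rt$dists, transitions)
  list(realtime = rt, smoothed = sm, primary = primary, secondary = secondary)
}
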