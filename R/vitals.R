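#' Estimate heart rate from a PPG window
#'
#' Systolic-peak detection on the 0.5-8 Hz band-passed PPG with an adaptive
#' (scale-invariant) threshold and a 250-ms refractory period; heart rate is
#' 60 over the median inter-beat interval. The estimate is flagged invalid
#' when fewer than 10 beats are found or the inter-beat-interval coefficient
#' of variation exceeds 0.5.
#'
#' @param ppg numeric PPG samples (>= 30 s).
#' @param rate sampling rate (Hz).
#' @return list with `hr_bpm`, `valid`, `n_beats`, `ibi_cv`.
#' @export
estimate_hr <- function(ppg, rate) {
  if (length(ppg) < 30 * rate) sl_error("PPG window must cover >= 30 s", "too_short")
  invalid <- list(hr_bpm = NA_real_, valid = FALSE, n_beats = 0L, ibi_cv = NA_real_)
  if (stats::sd(ppg) < 1e-12) return(invalid)
  x <- iir_bandpass(ppg, rate, 0.5, 8, order = 3)
  # local maxima above an amplitude-invariant threshold
  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  thr <- 0.4 * stats::quantile(x, 0.95, names = FALSE)
  cand <- which(is_peak & x > thr)
  if (!length(cand)) return(invalid)
  # enforce refractory: greedy left-to-right, keep the larger within 250 ms
  refr <- 0.25 * rate
  keep <- cand[1]
  for (p in cand[-1]) {
    last <- keep[length(keep)]
    if (p - last >= refr) {
      keep <- c(keep, p)
    } else if (x[p] > x[last]) {
      keep[length(keep)] <- p
    }
  }
  if (length(keep) < 11) return(invalid)
  ibi <- diff(keep) / rate
  cv <- stats::sd(ibi) / mean(ibi)
  list(
    hr_bpm = 60 / stats::median(ibi),
    valid = cv <= 0.5,
    n_beats = length(keep), ibi_cv = cv
  )
}

#' Estimate respiratory rate from an accelerometer window
#'
#' Gravity is removed by subtracting a 10-s moving average per axis; the
#' residual is projected onto its principal axis and the respiratory rate is
#' 60 times the dominant spectral frequency in the 0.1-0.5 Hz band (with
#' parabolic peak interpolation). The estimate is flagged invalid when the
#' post-gravity motion RMS exceeds `motion_max_g` (movement swamps the
#' respiratory modulation).
#'
#' @param acc n x 3 matrix (g), covering >= 60 s (two epochs).
#' @param rate sampling rate (Hz).
#' @param motion_max_g motion RMS validity threshold (g).
#' @return list with `rr_brpm`, `valid`, `motion_rms`.
#' @export
estimate_rr <- function(acc, rate, motion_max_g = 0.04) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 60 * rate) sl_error("ACC window must cover >= 60 s", "too_short")
  # respiration lives below 0.5 Hz: decimate to ~10 Hz by block averaging
  dec <- max(1L, as.integer(floor(rate / 10)))
  if (dec > 1) {
    nkeep <- floor(nrow(acc) / dec) * dec
    acc <- vapply(seq_len(3), function(j) {
      colMeans(matrix(acc[seq_len(nkeep), j], nrow = dec))
    }, numeric(nkeep / dec))
    rate <- rate / dec
  }
  g <- apply(acc, 2, moving_avg, n = as.integer(10 * rate))
  resid <- acc - g
  motion_rms <- sqrt(mean(rowSums(resid^2)))
  if (motion_rms > motion_max_g || motion_rms < 1e-9) {
    return(list(rr_brpm = NA_real_, valid = FALSE, motion_rms = motion_rms))
  }
  pc <- prcomp(resid, center = FALSE)
  x <- resid %*% pc$rotation[, 1]
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]^2
  f <- (seq_len(floor(n / 2)) - 1) * rate / n
  band <- which(f >= 0.1 & f <= 0.5)
  if (!length(band)) return(list(rr_brpm = NA_real_, valid = FALSE, motion_rms = motion_rms))
  i <- band[which.max(spec[band])]
  # parabolic interpolation around the peak bin
  fi <- f[i]
  if (i > 1 && i < length(f)) {
    a <- spec[i - 1]; b <- spec[i]; cc <- spec[i + 1]
    den <- a - 2 * b + cc
    if (abs(den) > 1e-12) fi <- f[i] + 0.5 * (a - cc) / den * (f[2] - f[1])
  }
  list(rr_brpm = 60 * fi, valid = TRUE, motion_rms = motion_rms)
}

#' Classify sleep posture from an accelerometer window
#'
#' The mean acceleration vector is matched to the nearest of five canonical
#' gravity orientations (supine, prone, left, right, upright) by angular
#' distance. Near-zero gravity magnitude is flagged invalid.
#'
#' @param acc n x 3 matrix (g).
#' @return list with `posture` (label or `NA`), `valid`, `angle_deg` to the
#'   chosen reference.
#' @export
classify_posture <- function(acc) {
  m <- colMeans(as.matrix(acc))
  nm <- sqrt(sum(m^2))
  if (nm < 0.3) return(list(posture = NA_character_, valid = FALSE, angle_deg = NA_real_))
  u <- m / nm
  ang <- vapply(POSTURE_REFS, function(r) {
    acos(pmin(1, pmax(-1, sum(u * r)))) * 180 / pi
  }, 0)
  best <- which.min(ang)
  list(posture = names(ang)[best], valid = TRUE, angle_deg = unname(ang[best]))
}

#' Per-epoch vitals series for a whole recording
#'
#' Heart rate per 30-s epoch from the PPG; respiratory rate from a trailing
#' two-epoch accelerometer window (value assigned to the trailing epoch, the
#' first epoch inherits the second's support); posture and motion RMS per
#' epoch.
#'
#' @param rec a [recording] with `ppg` and `acc`.
#' @return data frame with one row per epoch: `epoch` (0-based), `hr_bpm`,
#'   `hr_valid`, `rr_brpm`, `rr_valid`, `posture`, `posture_valid`,
#'   `motion_rms`.
#' @export
vitals_series <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(rec$ppg) || is.null(rec$acc)) {
    sl_error("recording lacks PPG and/or accelerometer data", "missing_modality")
  }
  np <- as.integer(rec$ppg_rate * 30)
  na <- as.integer(rec$acc_rate * 30)
  n_ep <- min(floor(length(rec$ppg) / np), floor(nrow(rec$acc) / na))
  rows <- lapply(seq_len(n_ep) - 1L, function(i) {
    hr <- estimate_hr(rec$ppg[(i * np + 1):((i + 1) * np)], rec$ppg_rate)
    j0 <- max(0L, min(i - 1L, n_ep - 2L))
    rr <- if (n_ep >= 2) {
      estimate_rr(rec$acc[(j0 * na + 1):((j0 + 2) * na), , drop = FALSE], rec$acc_rate)
    } else {
      list(rr_brpm = NA_real_, valid = FALSE, motion_rms = NA_real_)
    }
    po <- classify_posture(rec$acc[(i * na + 1):((i + 1) * na), , drop = FALSE])
    data.frame(
      epoch = i, hr_bpm = hr$hr_bpm, hr_valid = hr$valid,
      rr_brpm = rr$rr_brpm, rr_valid = rr$valid,
      posture = if (po$valid) po$posture else NA_character_,
      posture_valid = po$valid, motion_rms = rr$motion_rms
    )
  })
  do.call(rbind, rows)
}
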