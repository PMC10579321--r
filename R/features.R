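#' Spectral band definitions
#'
#' The four classical EEG bands used for relative spectral power: Delta
#' 0.5-4 Hz, Theta 4-8 Hz, Alpha 8-13 Hz, Beta 13-30 Hz (contiguous,
#' non-overlapping).
#'
#' @format data frame with columns `name`, `low`, `high`.
#' @export
BANDS <- data.frame(
  name = c("Delta", "Theta", "Alpha", "Beta"),
  low = c(0.5, 4, 8, 13),
  high = c(4, 8, 13, 30)
)

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed segments (default 4 s) with
#' 50\% overlap, mean-detrended per segment, one-sided density scaling.
#'
#' @param x numeric samples.
#' @param rate sampling rate (Hz).
#' @param seg_s segment length in seconds.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, rate, seg_s = 4) {
  nseg <- as.integer(seg_s * rate)
  n <- length(x)
  if (n < nseg) sl_error("signal shorter than one PSD segment", "too_short")
  step <- nseg %/% 2L
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1)))
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nseg - 1L)]
    (seg - mean(seg)) * w
  }, numeric(nseg))
  P <- Mod(stats::mvfft(segs))^2
  keep <- seq_len(nseg %/% 2L + 1L)
  psd <- rowMeans(P[keep, , drop = FALSE]) / (rate * sum(w^2))
  psd[c(-1, -length(psd))] <- 2 * psd[c(-1, -length(psd))]
  list(freq = (keep - 1) * rate / nseg, psd = psd)
}

#' Absolute and relative band powers of one epoch channel
#'
#' Band power is the PSD integral over each of the four bands in [BANDS];
#' relative power divides by the sum over the four bands, so the four
#' relative powers sum to one.
#'
#' @param x numeric samples (one 30-s window).
#' @param rate sampling rate (Hz).
#' @param psd optional precomputed [welch_psd] output.
#' @return list with `absolute` and `relative` (named numeric over the four
#'   bands), `total`, and the `psd`.
#' @export
band_powers <- function(x, rate, psd = NULL) {
  if (is.null(psd)) psd <- welch_psd(x, rate)
  df <- psd$freq[2] - psd$freq[1]
  absolute <- vapply(seq_len(nrow(BANDS)), function(i) {
    sel <- psd$freq > BANDS$low[i] & psd$freq <= BANDS$high[i]
    sum(psd$psd[sel]) * df
  }, 0)
  names(absolute) <- BANDS$name
  total <- sum(absolute)
  relative <- if (total > 0) absolute / total else rep(0.25, 4)
  names(relative) <- BANDS$name
  list(absolute = absolute, relative = relative, total = total, psd = psd)
}

# spectral entropy (normalized, 0.5-30 Hz) and 95% spectral edge from a PSD
spectral_summary <- function(psd) {
  sel <- psd$freq >= 0.5 & psd$freq <= 30
  p <- psd$psd[sel]
  if (sum(p) <= 0) return(c(entropy = 1, edge = 15))
  p <- p / sum(p)
  ent <- -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
  cum <- cumsum(p)
  edge <- psd$freq[sel][which(cum >= 0.95)[1]]
  c(entropy = ent, edge = edge)
}

#' Detect sleep spindles
#'
#' 11-16 Hz band-pass, 250-ms RMS envelope, events where the envelope exceeds
#' `k` times its median for 0.5-2 s. Each event reports its start time,
#' duration, peak frequency (from the event spectrum, 10-17 Hz) and maximum
#' peak-to-peak amplitude of the band-passed trace.
#'
#' @param x numeric samples (>= 30 s).
#' @param rate sampling rate (Hz).
#' @param k envelope threshold in multiples of the median envelope.
#' @return data frame with `t_start_s`, `duration_s`, `peak_frequency_hz`,
#'   `max_amplitude_uv`, ordered by start time.
#' @export
detect_spindles <- function(x, rate, k = 3) {
  empty <- data.frame(
    t_start_s = numeric(0), duration_s = numeric(0),
    peak_frequency_hz = numeric(0), max_amplitude_uv = numeric(0)
  )
  if (length(x) < 30 * rate) sl_error("signal must cover >= 30 s", "too_short")
  xb <- iir_bandpass(x, rate, 11, 16, order = 4)
  env <- sqrt(pmax(0, moving_avg(xb^2, as.integer(0.25 * rate))))
  thr <- k * stats::median(env)
  if (thr <= 0) return(empty)
  runs <- true_runs(env > thr)
  if (!nrow(runs)) return(empty)
  runs$dur <- (runs$end - runs$start + 1) / rate
  runs <- runs[runs$dur >= 0.5 & runs$dur <= 2, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    seg <- xb[runs$start[i]:runs$end[i]]
    nfft <- max(length(seg), as.integer(2 * rate))
    sp <- Mod(stats::fft(c(seg, numeric(nfft - length(seg)))))^2
    f <- (seq_len(nfft) - 1) * rate / nfft
    sel <- f >= 10 & f <= 17
    data.frame(
      t_start_s = (runs$start[i] - 1) / rate,
      duration_s = runs$dur[i],
      peak_frequency_hz = f[sel][which.max(sp[sel])],
      max_amplitude_uv = max(seg) - min(seg)
    )
  })
  do.call(rbind, out)
}

#' Detect slow waves
#'
#' 0.3-2 Hz band-pass, negative-to-positive zero-crossing segmentation;
#' negative half-waves with trough magnitude >= `min_trough_uv` and duration
#' 0.25-3.0 s are reported with their duration and trough magnitude.
#'
#' @param x numeric samples (>= 30 s).
#' @param rate sampling rate (Hz).
#' @param min_trough_uv amplitude criterion for the negative trough (uV).
#' @return data frame with `t_start_s`, `duration_s`, `negative_amplitude_uv`.
#' @export
detect_slow_waves <- function(x, rate, min_trough_uv = 40) {
  empty <- data.frame(
    t_start_s = numeric(0), duration_s = numeric(0),
    negative_amplitude_uv = numeric(0)
  )
  if (length(x) < 30 * rate) sl_error("signal must cover >= 30 s", "too_short")
  xb <- iir_bandpass(x, rate, 0.3, 2, order = 2)
  runs <- true_runs(xb < 0)
  if (!nrow(runs)) return(empty)
  runs$dur <- (runs$end - runs$start + 1) / rate
  trough <- vapply(seq_len(nrow(runs)), function(i) -min(xb[runs$start[i]:runs$end[i]]), 0)
  keep <- runs$dur >= 0.25 & runs$dur <= 3 & trough >= min_trough_uv
  if (!any(keep)) return(empty)
  data.frame(
    t_start_s = (runs$start[keep] - 1) / rate,
    duration_s = runs$dur[keep],
    negative_amplitude_uv = trough[keep]
  )
}

EXG_FEATURE_NAMES <- c(
  "rsp_delta", "rsp_theta", "rsp_alpha", "rsp_beta",
  "log_total_power", "spectral_entropy", "spectral_edge",
  "spindle_count", "spindle_amp", "sw_count", "sw_trough",
  "eog_low", "emg_power", "asym_alpha", "asym_delta", "asym_missing"
)

#' ExG feature vector for one epoch
#'
#' Channel-wise spectral features averaged over the usable derived channels,
#' hallmark-event summaries (spindles, slow waves) from the channel-mean
#' trace, a low-frequency EOG power feature from the forehead-target
#' channels, an EMG power feature (20-30 Hz), and left-right asymmetry terms
#' when both sides are usable (imputed with zero and flagged otherwise). The
#' feature ordering is fixed; the vector is invariant to channel input order.
#'
#' @param channels samples x derived-channels matrix (see [rereference]) or a
#'   named list of equal-length numeric vectors.
#' @param rate sampling rate (Hz).
#' @param events optional list with precomputed `spindles` and `slow_waves`
#'   data frames restricted to this epoch; detected on the channel mean when
#'   omitted.
#' @return named numeric vector in the order `EXG_FEATURE_NAMES`.
#' @export
exg_feature_vector <- function(channels, rate, events = NULL) {
  if (is.list(channels) && !is.matrix(channels)) {
    channels <- do.call(cbind, channels)
  }
  if (is.null(colnames(channels)) || ncol(channels) == 0) {
    sl_error("at least one named usable channel is required", "no_usable_channels")
  }
  channels <- channels[, order(colnames(channels)), drop = FALSE]
  # derived-channel names are "<target>-<reference>"; raw pass-through keeps
  # the bare target label
  targets <- stats::setNames(sub("-.*$", "", colnames(channels)), colnames(channels))

  per_ch <- lapply(seq_len(ncol(channels)), function(c) {
    bp <- band_powers(channels[, c], rate)
    ss <- spectral_summary(bp$psd)
    df <- bp$psd$freq[2] - bp$psd$freq[1]
    emg_sel <- bp$psd$freq >= 20 & bp$psd$freq <= 30
    eog_sel <- bp$psd$freq >= 0.3 & bp$psd$freq <= 4
    list(
      rel = bp$relative, total = bp$total, ent = ss[["entropy"]], edge = ss[["edge"]],
      emg = sum(bp$psd$psd[emg_sel]) * df,
      eog = sum(bp$psd$psd[eog_sel]) * df
    )
  })
  names(per_ch) <- colnames(channels)
  relm <- t(vapply(per_ch, function(p) p$rel, numeric(4)))
  rel_mean <- colMeans(relm)

  mean_trace <- rowMeans(channels)
  if (is.null(events)) {
    sp <- detect_spindles(mean_trace, rate)
    sw <- detect_slow_waves(mean_trace, rate)
  } else {
    sp <- events$spindles
    sw <- events$slow_waves
  }

  side <- ifelse(grepl("_L$", targets), "L", "R")
  asym_alpha <- asym_delta <- 0
  asym_missing <- 1
  if (all(c("L", "R") %in% side)) {
    asym_alpha <- mean(relm[side == "L", "Alpha"]) - mean(relm[side == "R", "Alpha"])
    asym_delta <- mean(relm[side == "L", "Delta"]) - mean(relm[side == "R", "Delta"])
    asym_missing <- 0
  }
  fh <- which(targets %in% c("FH_L", "FH_R"))
  eog <- if (length(fh)) mean(vapply(per_ch[fh], function(p) p$eog, 0)) else
    mean(vapply(per_ch, function(p) p$eog, 0))

  out <- c(
    rsp_delta = rel_mean[["Delta"]], rsp_theta = rel_mean[["Theta"]],
    rsp_alpha = rel_mean[["Alpha"]], rsp_beta = rel_mean[["Beta"]],
    log_total_power = log1p(mean(vapply(per_ch, function(p) p$total, 0))),
    spectral_entropy = mean(vapply(per_ch, function(p) p$ent, 0)),
    spectral_edge = mean(vapply(per_ch, function(p) p$edge, 0)),
    spindle_count = nrow(sp),
    spindle_amp = if (nrow(sp)) mean(sp$max_amplitude_uv) else 0,
    sw_count = nrow(sw),
    sw_trough = if (nrow(sw)) mean(sw$negative_amplitude_uv) else 0,
    eog_low = log1p(eog),
    emg_power = log1p(mean(vapply(per_ch, function(p) p$emg, 0))),
    asym_alpha = asym_alpha, asym_delta = asym_delta,
    asym_missing = asym_missing
  )
  out[EXG_FEATURE_NAMES]
}
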