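#' Channel-quality thresholds
#'
#' Screening thresholds deciding whether an epoch of a channel is scorable.
#' A channel fails when any metric crosses its threshold: too much flatline,
#' rail saturation, high-amplitude excursions, implausible RMS, or dominant
#' mains-band noise.
#'
#' @param flatline_frac max tolerated fraction of near-constant samples.
#' @param saturation_frac max tolerated fraction of samples at the rails.
#' @param highamp_frac max tolerated fraction of 1-s windows whose
#'   peak-to-peak exceeds `ptp_uv`.
#' @param rms_min,rms_max plausible RMS range (uV).
#' @param line_ratio max tolerated 45-55 Hz power over 0.3-35 Hz power.
#' @param sat_uv absolute amplitude treated as rail contact (uV).
#' @param ptp_uv peak-to-peak threshold for the high-amplitude screen (uV).
#' @param flat_uv chunk SD below which 0.5-s chunks count as flat (uV).
#' @return named list of thresholds.
#' @export
quality_thresholds <- function(flatline_frac = 0.2, saturation_frac = 0.05,
                               highamp_frac = 0.3, rms_min = 0.5, rms_max = 150,
                               line_ratio = 1.0, sat_uv = 450, ptp_uv = 500,
                               flat_uv = 0.2) {
  as.list(environment())
}

# metrics from pre-computed pieces; shared by the per-window and whole-night
# paths so both produce identical decisions
quality_from_metrics <- function(rms, flat, sat, high, line, th) {
  data.frame(
    rms_uv = rms, flatline_frac = flat, saturation_frac = sat,
    highamp_frac = high, line_noise_ratio = line,
    scorable = !(flat > th$flatline_frac | sat > th$saturation_frac |
                   high > th$highamp_frac | rms < th$rms_min | rms > th$rms_max |
                   line > th$line_ratio)
  )
}

chunk_stat <- function(x, chunk, fun) {
  m <- matrix(x, nrow = chunk)
  fun(m)
}

#' Assess one epoch of one channel
#'
#' Computes the screening metrics on a single 30-s window and applies the
#' thresholds. `scorable` is `FALSE` iff any metric crosses its threshold.
#'
#' @param window numeric vector of length `rate * 30` (uV).
#' @param rate sampling rate (Hz).
#' @param thresholds a [quality_thresholds] list.
#' @return one-row data frame with the metrics and `scorable`.
#' @export
assess_channel <- function(window, rate, thresholds = quality_thresholds()) {
  if (length(window) != rate * 30) {
    sl_error("window length must equal rate * 30", "invalid_window")
  }
  th <- thresholds
  rms <- stats::sd(window)
  half <- as.integer(rate / 2)
  flat_chunks <- chunk_stat(window, half, function(m) {
    sqrt(pmax(0, colMeans(m^2) - colMeans(m)^2)) < th$flat_uv
  })
  flat <- mean(flat_chunks)
  sat <- mean(abs(window) >= th$sat_uv)
  ptp <- chunk_stat(window, as.integer(rate), function(m) col_maxs(m) - col_mins(m))
  high <- mean(ptp > th$ptp_uv)
  line <- if (rate > 112 && rms > 0) {
    P <- Mod(stats::fft(window - mean(window)))^2
    ff <- pmin((seq_along(P) - 1), length(P) - (seq_along(P) - 1)) * rate / length(P)
    sum(P[ff >= 45 & ff <= 55]) / max(sum(P[ff >= 0.3 & ff <= 35]), 1e-12)
  } else 0
  quality_from_metrics(rms, flat, sat, high, line, th)
}

#' Assess every epoch and channel of a recording
#'
#' Whole-night vectorized equivalent of [assess_channel]: metrics are
#' computed per 30-s epoch for each of the six ExG channels, with the
#' mains-band ratio taken from the continuously filtered signal.
#'
#' @param rec a [recording].
#' @param thresholds a [quality_thresholds] list.
#' @return data frame with `epoch` (0-based), `channel`, the metrics, and
#'   `scorable`.
#' @export
assess_recording <- function(rec, thresholds = quality_thresholds()) {
  stopifnot(inherits(rec, "recording"))
  th <- thresholds
  fs <- rec$exg_rate
  ns <- as.integer(fs * 30)
  n_ep <- floor(nrow(rec$exg) / ns)
  if (n_ep < 1) sl_error("recording shorter than one epoch", "too_short")
  half <- as.integer(fs / 2)
  out <- vector("list", 6)
  for (c in seq_len(6)) {
    x <- rec$exg[seq_len(n_ep * ns), c]
    m <- matrix(x, nrow = ns)
    rms <- sqrt(pmax(0, colMeans(m^2) - colMeans(m)^2))
    chunk_sd <- sqrt(pmax(0, colMeans(matrix(x, nrow = half)^2) -
                            colMeans(matrix(x, nrow = half))^2))
    flat <- colMeans(matrix(chunk_sd < th$flat_uv, nrow = ns / half))
    sat <- colMeans(matrix(abs(x) >= th$sat_uv, nrow = ns))
    pm <- matrix(x, nrow = as.integer(fs))
    ptp <- col_maxs(pm) - col_mins(pm)
    high <- colMeans(matrix(ptp > th$ptp_uv, nrow = 30))
    line <- if (fs > 112) {
      mc <- sweep(m, 2, colMeans(m))
      P <- Mod(stats::mvfft(mc))^2
      ff <- pmin((seq_len(ns) - 1), ns - (seq_len(ns) - 1)) * fs / ns
      colSums(P[ff >= 45 & ff <= 55, , drop = FALSE]) /
        pmax(colSums(P[ff >= 0.3 & ff <= 35, , drop = FALSE]), 1e-12)
    } else rep(0, n_ep)
    q <- quality_from_metrics(rms, flat, sat, high, line, th)
    q <- cbind(epoch = seq_len(n_ep) - 1L, channel = EXG_CHANNELS[c], q)
    out[[c]] <- q
  }
  grid <- do.call(rbind, out)
  grid[order(grid$epoch, match(grid$channel, EXG_CHANNELS)), , drop = FALSE]
}

#' Usable channels of one epoch
#'
#' @param quality_row data frame with one row per ExG channel (columns
#'   `channel` and `scorable`), or a named logical vector.
#' @return character vector of scorable channel labels (possibly empty: the
#'   epoch is then ExG-unscorable).
#' @export
select_channels <- function(quality_row) {
  if (is.data.frame(quality_row)) {
    quality_row$channel[quality_row$scorable]
  } else {
    names(quality_row)[quality_row]
  }
}

# contralateral / ipsilateral bone-electrode references per target channel
REREF_TARGETS <- c("FH_L", "FH_R", "OTE_L", "OTE_R")
CONTRA_BE <- c(FH_L = "BE_R", FH_R = "BE_L", OTE_L = "BE_R", OTE_R = "BE_L")
IPSI_BE <- c(FH_L = "BE_L", FH_R = "BE_R", OTE_L = "BE_L", OTE_R = "BE_R")

#' Derive re-referenced virtual channels for one epoch
#'
#' Three schemes: `"none"` passes usable channels through unchanged;
#' `"contralateral_be"` re-references each forehead/over-the-ear channel to
#' the bone electrode on the opposite side, emitting a derived channel only
#' when both members are usable; `"dynamic"` applies a fixed fallback chain
#' per target channel — contralateral BE if usable, else ipsilateral BE, else
#' the raw channel — so a derived channel exists whenever the target itself
#' is usable.
#'
#' @param exg samples x channels matrix for one epoch (the six ExG columns).
#' @param usable character vector of usable channel labels.
#' @param scheme `"dynamic"`, `"contralateral_be"` or `"none"`.
#' @return samples x derived-channels matrix; attribute `refs` names the
#'   reference used for each derived channel (`"raw"` for pass-through), and
#'   attribute `target` the underlying target channel.
#' @export
rereference <- function(exg, usable, scheme = c("dynamic", "contralateral_be", "none")) {
  scheme <- match.arg(scheme)
  if (length(bad <- setdiff(usable, EXG_CHANNELS))) {
    sl_error(paste0("unknown channel(s): ", paste(bad, collapse = ", ")), "invalid_channel")
  }
  cols <- list(); refs <- character(); targets <- character()
  emit <- function(target, ref) {
    x <- if (is.na(ref)) exg[, target] else exg[, target] - exg[, ref]
    nm <- if (is.na(ref)) target else paste0(target, "-", ref)
    cols[[nm]] <<- x
    refs[nm] <<- if (is.na(ref)) "raw" else ref
    targets[nm] <<- target
  }
  if (scheme == "none") {
    for (ch in intersect(EXG_CHANNELS, usable)) emit(ch, NA)
  } else if (scheme == "contralateral_be") {
    for (ch in REREF_TARGETS) {
      if (ch %in% usable && CONTRA_BE[[ch]] %in% usable) emit(ch, CONTRA_BE[[ch]])
    }
  } else {
    for (ch in intersect(REREF_TARGETS, usable)) {
      if (CONTRA_BE[[ch]] %in% usable) {
        emit(ch, CONTRA_BE[[ch]])
      } else if (IPSI_BE[[ch]] %in% usable) {
        emit(ch, IPSI_BE[[ch]])
      } else {
        emit(ch, NA)
      }
    }
  }
  if (!length(cols)) {
    m <- matrix(numeric(0), nrow = nrow(exg), ncol = 0)
  } else {
    m <- do.call(cbind, cols)
    colnames(m) <- names(cols)
  }
  attr(m, "refs") <- refs
  attr(m, "target") <- targets
  m
}

#' Summarize channel availability
#'
#' Per-channel fail ratio (fraction of unscorable epochs) and, when artifact
#' events are supplied, the stabilization time of each event: the delay from
#' the end of the injected artifact to the first subsequent scorable epoch on
#' that channel.
#'
#' @param grid output of [assess_recording].
#' @param events optional data frame (`channel`, `start_epoch`, `n_epochs`).
#' @return list with `fail_ratio` (named per channel) and `stabilization`
#'   (data frame with one row per event; `stabilization_s` is `NA` when the
#'   channel never recovers before the recording ends).
#' @export
summarize_quality <- function(grid, events = NULL) {
  fail_ratio <- vapply(EXG_CHANNELS, function(ch) {
    g <- grid[grid$channel == ch, ]
    mean(!g$scorable)
  }, 0)
  stab <- NULL
  if (!is.null(events) && nrow(events)) {
    n_ep <- max(grid$epoch) + 1L
    stab <- do.call(rbind, lapply(seq_len(nrow(events)), function(k) {
      e <- events[k, ]
      end_ep <- min(n_ep - 1L, e$start_epoch + e$n_epochs - 1L)
      g <- grid[grid$channel == e$channel & grid$epoch > end_ep, ]
      ok <- g$epoch[g$scorable]
      data.frame(
        channel = e$channel, end_epoch = end_ep,
        stabilization_s = if (length(ok)) (min(ok) - end_ep - 1L) * 30 else NA_real_
      )
    }))
  }
  list(fail_ratio = fail_ratio, stabilization = stab)
}
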