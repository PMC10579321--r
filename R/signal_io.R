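#' Multimodal wearable recording
#'
#' Container for one synchronized recording session: six ExG biopotential
#' channels (microvolts), one PPG channel (arbitrary optical units) and a
#' 3-axis accelerometer (g), each with its own sampling rate.
#'
#' @param exg numeric matrix, one column per ExG channel; column names must be
#'   the six device labels `FH_L, FH_R, OTE_L, OTE_R, BE_L, BE_R`.
#' @param exg_rate ExG sampling rate in Hz (default 200).
#' @param ppg numeric vector of PPG samples, or `NULL`.
#' @param ppg_rate PPG sampling rate in Hz.
#' @param acc numeric matrix with 3 columns (x, y, z in g), or `NULL`.
#' @param acc_rate accelerometer sampling rate in Hz.
#' @param start_time recording start (`POSIXct`).
#' @param meta free-form named list.
#' @return an object of class `"recording"`.
#' @export
recording <- function(exg, exg_rate = 200, ppg = NULL, ppg_rate = 64,
                      acc = NULL, acc_rate = 50,
                      start_time = as.POSIXct("2000-01-01 22:00:00", tz = "UTC"),
                      meta = list()) {
  exg <- as.matrix(exg)
  if (is.null(colnames(exg)) || anyDuplicated(colnames(exg))) {
    sl_error("exg columns must carry unique channel labels", "invalid_recording")
  }
  missing <- setdiff(EXG_CHANNELS, colnames(exg))
  if (length(missing)) {
    sl_error(
      paste0("missing ExG channel(s): ", paste(missing, collapse = ", ")),
      "missing_channel"
    )
  }
  rates <- c(exg_rate, ppg_rate, acc_rate)
  if (any(rates <= 0)) sl_error("sampling rates must be positive", "invalid_recording")
  if (!is.null(acc)) {
    acc <- as.matrix(acc)
    if (ncol(acc) != 3) sl_error("acc must have 3 columns", "invalid_recording")
  }
  dur <- nrow(exg) / exg_rate
  for (m in list(list(ppg, ppg_rate, "ppg"), list(acc, acc_rate, "acc"))) {
    if (!is.null(m[[1]])) {
      d <- NROW(m[[1]]) / m[[2]]
      if (abs(d - dur) > 1 / min(exg_rate, m[[2]])) {
        sl_error(
          sprintf("%s duration (%.2fs) inconsistent with ExG (%.2fs)", m[[3]], d, dur),
          "invalid_recording"
        )
      }
    }
  }
  structure(
    list(
      exg = exg[, EXG_CHANNELS, drop = FALSE], exg_rate = exg_rate,
      ppg = ppg, ppg_rate = ppg_rate, acc = acc, acc_rate = acc_rate,
      start_time = start_time, meta = meta
    ),
    class = "recording"
  )
}

#' @rdname recording
#' @export
EXG_CHANNELS <- c("FH_L", "FH_R", "OTE_L", "OTE_R", "BE_L", "BE_R")

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %.1f min ExG @ %g Hz (%d ch)%s%s\n",
    nrow(x$exg) / x$exg_rate / 60, x$exg_rate, ncol(x$exg),
    if (!is.null(x$ppg)) sprintf(", PPG @ %g Hz", x$ppg_rate) else "",
    if (!is.null(x$acc)) sprintf(", ACC @ %g Hz", x$acc_rate) else ""
  ))
  invisible(x)
}

recording_duration_s <- function(rec) nrow(rec$exg) / rec$exg_rate

## ---------------------------------------------------------------------------
## EDF container
##
## Minimal European Data Format support: ASCII header, one 16-bit
## little-endian integer stream per signal, 30-s data records (so record
## boundaries coincide with scoring epochs). Physical units are taken from
## the per-signal dimension field; ExG channels are converted to microvolts
## on read.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(signif(x, width - 2), format = "g", width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Signals are stored under the labels `FH_L, FH_R, OTE_L, OTE_R, BE_L, BE_R`
#' (microvolts), `PPG` and `ACC_X/ACC_Y/ACC_Z` (g), with 30-s data records.
#' The trailing partial record, if any, is dropped.
#'
#' @param rec a [recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  rec_dur <- 30
  sigs <- list()
  for (ch in colnames(rec$exg)) {
    sigs[[ch]] <- list(x = rec$exg[, ch], rate = rec$exg_rate, dim = "uV")
  }
  if (!is.null(rec$ppg)) sigs[["PPG"]] <- list(x = rec$ppg, rate = rec$ppg_rate, dim = "a.u.")
  if (!is.null(rec$acc)) {
    for (i in 1:3) {
      sigs[[c("ACC_X", "ACC_Y", "ACC_Z")[i]]] <-
        list(x = rec$acc[, i], rate = rec$acc_rate, dim = "g")
    }
  }
  n_rec <- floor(min(vapply(sigs, function(s) length(s$x) / s$rate, 0)) / rec_dur)
  if (n_rec < 1) sl_error("recording shorter than one 30-s record", "too_short")
  ns <- length(sigs)

  spr <- integer(ns); dig <- vector("list", ns)
  pmin_ <- pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    s <- sigs[[i]]
    if (abs(s$rate * rec_dur - round(s$rate * rec_dur)) > 1e-9) {
      sl_error("sampling rate must yield integer samples per 30-s record", "invalid_recording")
    }
    spr[i] <- as.integer(round(s$rate * rec_dur))
    x <- s$x[seq_len(n_rec * spr[i])]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-9) { hi <- lo + 1 }
    pmin_[i] <- lo; pmax_[i] <- hi
    dig[[i]] <- matrix(
      as.integer(round((x - lo) / (hi - lo) * 65535 - 32768)),
      nrow = spr[i]
    )
  }

  st <- as.POSIXlt(rec$start_time)
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad(sprintf("%02d.%02d.%02d", st$mday, st$mon + 1, st$year %% 100), 8),
    edf_pad(sprintf("%02d.%02d.%02d", st$hour, st$min, floor(st$sec)), 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(rec_dur, 8), edf_pad(ns, 4)
  )
  field <- function(f, width) paste(vapply(seq_len(ns), f, ""), collapse = "")
  hdr <- paste0(
    hdr,
    field(function(i) edf_pad(names(sigs)[i], 16), 16),
    field(function(i) edf_pad("", 80), 80),
    field(function(i) edf_pad(sigs[[i]]$dim, 8), 8),
    field(function(i) edf_num(pmin_[i], 8), 8),
    field(function(i) edf_num(pmax_[i], 8), 8),
    field(function(i) edf_pad(-32768, 8), 8),
    field(function(i) edf_pad(32767, 8), 8),
    field(function(i) edf_pad("", 80), 80),
    field(function(i) edf_pad(spr[i], 8), 8),
    field(function(i) edf_pad("", 32), 32)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  # record-major interleaving: rbind per-signal record matrices
  data <- do.call(rbind, dig)
  writeBin(as.integer(data), con, size = 2, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80) # version + patient + recording id
  date <- rd(8); time <- rd(8)
  rd(8 + 44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  fld <- function(width) trimws(vapply(seq_len(ns), function(i) rd(width), ""))
  labels <- fld(16); fld(80)
  dims <- fld(8)
  p_min <- as.numeric(fld(8)); p_max <- as.numeric(fld(8))
  d_min <- as.numeric(fld(8)); d_max <- as.numeric(fld(8))
  fld(80); spr <- as.integer(fld(8)); fld(32)

  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr)) sl_error("truncated EDF data", "io_error")
  data <- matrix(raw, nrow = sum(spr))
  offs <- c(0L, cumsum(spr))
  out <- vector("list", ns)
  scale <- (p_max - p_min) / (d_max - d_min)
  for (i in seq_len(ns)) {
    d <- as.vector(data[(offs[i] + 1):offs[i + 1], , drop = FALSE])
    out[[i]] <- (d - d_min[i]) * scale[i] + p_min[i]
  }
  names(out) <- labels
  start <- tryCatch(
    as.POSIXct(paste(date, time), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NA
  )
  list(
    signals = out, labels = labels, rates = spr / rec_dur, dims = dims,
    start_time = start, n_records = n_rec, record_duration = rec_dur
  )
}

#' Read a recording from an EDF file
#'
#' The six ExG labels must be present; PPG and accelerometer channels are
#' picked up when available, and any unknown signals are preserved in
#' `meta$extra`. ExG channels stored in mV or V are converted to microvolts.
#'
#' @param path path to an EDF file.
#' @return a [recording].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) sl_error(paste0("cannot read: ", path), "io_error")
  edf <- read_edf(path)
  missing <- setdiff(EXG_CHANNELS, edf$labels)
  if (length(missing)) {
    sl_error(
      paste0("missing ExG channel(s): ", paste(missing, collapse = ", ")),
      "missing_channel"
    )
  }
  to_uv <- function(x, dim) {
    switch(tolower(dim), "mv" = x * 1e3, "v" = x * 1e6, x)
  }
  exg <- sapply(EXG_CHANNELS, function(ch) {
    i <- match(ch, edf$labels)
    to_uv(edf$signals[[i]], edf$dims[i])
  })
  exg_rate <- unique(edf$rates[match(EXG_CHANNELS, edf$labels)])
  if (length(exg_rate) != 1) sl_error("ExG channels disagree on sampling rate", "invalid_recording")
  ppg <- NULL; ppg_rate <- 64
  if ("PPG" %in% edf$labels) {
    i <- match("PPG", edf$labels)
    ppg <- edf$signals[[i]]; ppg_rate <- edf$rates[i]
  }
  acc <- NULL; acc_rate <- 50
  acc_labels <- c("ACC_X", "ACC_Y", "ACC_Z")
  if (all(acc_labels %in% edf$labels)) {
    ii <- match(acc_labels, edf$labels)
    acc <- do.call(cbind, edf$signals[ii]); colnames(acc) <- acc_labels
    acc_rate <- edf$rates[ii[1]]
  }
  extra <- setdiff(edf$labels, c(EXG_CHANNELS, "PPG", acc_labels))
  meta <- list()
  if (length(extra)) meta$extra <- edf$signals[extra]
  recording(
    exg = exg, exg_rate = exg_rate, ppg = ppg, ppg_rate = ppg_rate,
    acc = acc, acc_rate = acc_rate,
    start_time = if (is.na(edf$start_time)) Sys.time() else edf$start_time,
    meta = meta
  )
}

## ---------------------------------------------------------------------------
## Epoch partitioning

#' Partition a recording into 30-s epochs
#'
#' Epoch `i` (0-based) covers the half-open window `[30i, 30i + 30)` seconds;
#' a trailing partial epoch is discarded.
#'
#' @param rec a [recording].
#' @return list of epoch views, each a list with `index` (0-based),
#'   `t_start_s`, `exg` (samples x channels), and `ppg`/`acc` windows when
#'   those modalities are present.
#' @export
epochize <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  dur <- recording_duration_s(rec)
  if (dur < 30) sl_error("recording shorter than one 30-s epoch", "too_short")
  n_ep <- floor(dur / 30)
  ne <- rec$exg_rate * 30
  np <- if (!is.null(rec$ppg)) rec$ppg_rate * 30 else 0
  na <- if (!is.null(rec$acc)) rec$acc_rate * 30 else 0
  lapply(seq_len(n_ep) - 1L, function(i) {
    ev <- list(
      index = i, t_start_s = 30 * i,
      exg = rec$exg[(i * ne + 1):((i + 1) * ne), , drop = FALSE],
      exg_rate = rec$exg_rate
    )
    if (np > 0) {
      ev$ppg <- rec$ppg[(i * np + 1):((i + 1) * np)]
      ev$ppg_rate <- rec$ppg_rate
    }
    if (na > 0) {
      ev$acc <- rec$acc[(i * na + 1):((i + 1) * na), , drop = FALSE]
      ev$acc_rate <- rec$acc_rate
    }
    class(ev) <- "epoch_view"
    ev
  })
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain filter with hard band edges: the Fourier spectrum is
#' masked outside `[low, high]` and inverted. Zero phase (no group delay),
#' output length equals input length, and the operation is exactly idempotent.
#' The package default band, 0.3-35 Hz, matches the clinical reference
#' acquisition chain for sleep EEG.
#'
#' @param x numeric samples.
#' @param rate sampling rate (Hz).
#' @param low,high band edges in Hz; `0 < low < high < rate/2`.
#' @return filtered samples, same length as `x`.
#' @export
bandpass <- function(x, rate, low = 0.3, high = 35) {
  if (!(low > 0 && high > low && high < rate / 2)) {
    sl_error("band must satisfy 0 < low < high < rate/2", "invalid_band")
  }
  n <- length(x)
  if (n == 0) return(x)
  f <- (seq_len(n) - 1) * rate / n
  f_fold <- pmin(f, rate - f)
  mask <- f_fold >= low & f_fold <= high
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

## ---------------------------------------------------------------------------
## Hypnogram CSV

#' Read / write hypnogram CSV files
#'
#' On-disk format: header `epoch,stage`, one row per 30-s epoch, stage codes
#' `W`, `LS`, `DS`, `R` (REM) and `U` (unscored).
#'
#' @param path CSV file path.
#' @param h a [hypnogram].
#' @return `read_hypnogram` returns a [hypnogram]; `write_hypnogram` returns
#'   `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) sl_error(paste0("cannot read: ", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"stage" %in% names(df)) sl_error("hypnogram CSV needs a 'stage' column", "parse_error")
  codes <- as.character(df$stage)
  bad <- which(!codes %in% names(STAGE_FROM_CODE))
  if (length(bad)) {
    sl_error(
      sprintf("unknown stage code '%s' at row %d", codes[bad[1]], bad[1]),
      "parse_error"
    )
  }
  hypnogram(unname(STAGE_FROM_CODE[codes]))
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(is_hypnogram(h))
  df <- data.frame(
    epoch = seq_along(h) - 1L,
    stage = unname(STAGE_CODES[unclass(h)])
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
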