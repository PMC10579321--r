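# internal helpers shared across modules

sl_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "somnoloop_error", "error", "condition")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# column maxima / minima of a matrix without apply() overhead
col_maxs <- function(m) Reduce(pmax, asplit(m, 1))
col_mins <- function(m) Reduce(pmin, asplit(m, 1))

# trailing moving average via stats::filter (centered), edges padded with
# the nearest interior value
moving_avg <- function(x, n) {
  if (n <= 1) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
  idx <- which(!is.na(y))
  if (!length(idx)) return(rep(mean(x), length(x)))
  y[seq_len(idx[1] - 1)] <- y[idx[1]]
  last <- idx[length(idx)]
  if (last < length(y)) y[(last + 1):length(y)] <- y[last]
  y
}

# runs of TRUE in a logical vector -> data.frame(start, end) (1-based, inclusive)
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# zero-phase Butterworth band-pass via filtfilt; used by feature detectors
iir_bandpass <- function(x, rate, low, high, order = 4) {
  ny <- rate / 2
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  signal::filtfilt(bf, x)
}

iir_lowpass <- function(x, rate, cutoff, order = 2) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  signal::filtfilt(bf, x)
}

# approximate 1/f ("pink") background noise: sum of octave-spaced one-pole
# low-passed white noise streams, rescaled to unit SD
pink_noise <- function(n, rate) {
  if (n == 0) return(numeric(0))
  corners <- c(0.3, 1.2, 5, 20)
  corners <- corners[corners < rate / 2]
  y <- numeric(n)
  for (fc in corners) {
    a <- exp(-2 * pi * fc / rate)
    y <- y + as.numeric(stats::filter(stats::rnorm(n) * (1 - a), a, method = "recursive"))
  }
  s <- stats::sd(y)
  if (s > 0) y / s else y
}
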