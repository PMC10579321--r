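# shared expensive fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# 50-night benchmark pool (40 train + 10 held out) and models trained on it
benchmark_pool <- function() {
  get_fixture("pool50", function() {
    build_night_set(50, sim_config(duration_min = 90), seed_base = 101)
  })
}

benchmark_models <- function() {
  get_fixture("models50", function() {
    train_on_nights(benchmark_pool()[1:40], seed = 1)
  })
}

small_night <- function() {
  get_fixture("small_night", function() {
    simulate_night(sim_config(seed = 42, duration_min = 30))
  })
}

# bare stage vector of a hypnogram (drops class and attributes)
stages_of <- function(h) as.vector(unclass(h))

# list of hypnograms from the columns of a stage matrix
hyp_cols <- function(m) lapply(seq_len(ncol(m)), function(j) hypnogram(m[, j]))

# brute-force maximum a posteriori path by exhaustive enumeration
brute_force_path <- function(emit, trans, init) {
  n <- nrow(emit)
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))
  lp <- log(init[paths[, 1]]) + log(emit[1, ][paths[, 1]])
  if (n > 1) {
    for (t in 2:n) {
      lp <- lp + log(trans[cbind(paths[, t - 1], paths[, t])]) +
        log(emit[t, ][paths[, t]])
    }
  }
  paths[which.max(lp), ]
}

# independent consensus oracle: naive per-epoch vote counting plus explicit
# pairwise-agreement tie-break
oracle_consensus <- function(m) {
  k <- ncol(m)
  pair_agree <- matrix(0, k, k)
  for (a in 1:k) {
    for (b in 1:k) {
      if (a != b) pair_agree[a, b] <- sum(m[, a] == m[, b]) / nrow(m)
    }
  }
  best <- which.max(rowSums(pair_agree) / (k - 1))
  out <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    votes <- m[i, ]
    counts <- vapply(unique(votes), function(v) sum(votes == v), 0L)
    winners <- names(counts)[counts == max(counts)]
    out[i] <- if (length(winners) == 1) winners else votes[best]
  }
  out
}

# windowed oscillatory burst with a flat top (short cosine ramps), so the
# suprathreshold run matches the nominal duration
flat_top_burst <- function(n, fs, t0, dur, freq, amp, ramp = 0.1) {
  x <- numeric(n)
  i0 <- floor(t0 * fs) + 1
  len <- round(dur * fs)
  idx <- i0:(i0 + len - 1)
  u <- seq(0, 1, length.out = len)
  env <- rep(1, len)
  r <- ramp / dur
  env[u < r] <- 0.5 * (1 - cos(pi * u[u < r] / r))
  env[u > 1 - r] <- 0.5 * (1 - cos(pi * (1 - u[u > 1 - r]) / r))
  x[idx] <- amp * env * sin(2 * pi * freq * (idx - i0) / fs)
  x
}

# TRUE iff no single epoch differs from two equal flanking epochs (the
# pattern the smoother's rule pass removes)
no_flanked_islands <- function(s) {
  n <- length(s)
  if (n < 3) return(TRUE)
  i <- 2:(n - 1)
  !any(s[i - 1] == s[i + 1] & s[i] != s[i - 1])
}
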