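#' Consensus hypnogram from multiple technician scorings
#'
#' Per epoch, the maximally voted stage. When the vote is tied (no unique
#' maximum), the epoch is scored according to the technician with the highest
#' mean pairwise epoch-agreement over the whole study; a residual tie among
#' technicians is broken by the lowest technician index.
#'
#' @param hyps list of >= 3 [hypnogram]s of equal length.
#' @return the consensus [hypnogram].
#' @export
consensus_hypnogram <- function(hyps) {
  if (length(hyps) < 3) sl_error("need at least 3 technician hypnograms", "too_few_scorers")
  lens <- vapply(hyps, length, 0L)
  if (length(unique(lens)) != 1) sl_error("hypnograms must have equal length", "length_mismatch")
  m <- vapply(hyps, unclass, character(lens[1])) # epochs x technicians
  if (lens[1] == 1) m <- matrix(m, nrow = 1)
  k <- ncol(m)
  # mean pairwise agreement per technician
  agree <- matrix(0, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      agree[a, b] <- agree[b, a] <- mean(m[, a] == m[, b])
    }
  }
  mean_agree <- rowSums(agree) / (k - 1)
  best_tech <- which.max(mean_agree) # ties -> lowest index (which.max semantics)
  out <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    tab <- table(m[i, ])
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1) top else m[i, best_tech]
  }
  hypnogram(out)
}

#' Fit a stage transition model
#'
#' Maximum-likelihood bigram counts over consecutive scored epochs, with
#' additive smoothing `eps` and row renormalization. The initial distribution
#' is the smoothed frequency of first-epoch stages.
#'
#' @param hyps list of [hypnogram]s (or a single hypnogram).
#' @param eps additive smoothing constant; with `eps = 0` unseen transitions
#'   keep probability 0.
#' @return list of class `"transition_model"` with `matrix` (4x4) and
#'   `initial`.
#' @export
fit_transitions <- function(hyps, eps = 1e-4) {
  if (is_hypnogram(hyps)) hyps <- list(hyps)
  counts <- matrix(0, 4, 4, dimnames = list(STAGES, STAGES))
  init <- stats::setNames(numeric(4), STAGES)
  for (h in hyps) {
    s <- unclass(h)
    s <- s[s != UNSCORED]
    if (!length(s)) next
    init[s[1]] <- init[s[1]] + 1
    if (length(s) > 1) {
      for (i in seq_len(length(s) - 1)) {
        counts[s[i], s[i + 1]] <- counts[s[i], s[i + 1]] + 1
      }
    }
  }
  counts <- counts + eps
  rs <- rowSums(counts)
  mat <- counts / ifelse(rs > 0, rs, 1)
  mat[rs == 0, ] <- 0.25
  init <- init + eps
  init <- if (sum(init) > 0) init / sum(init) else rep(0.25, 4)
  structure(list(matrix = mat, initial = init, eps = eps), class = "transition_model")
}

# log-space Viterbi decoding; emissions n x 4, returns stage indices
viterbi_path <- function(log_emit, log_trans, log_init) {
  n <- nrow(log_emit)
  delta <- log_init + log_emit[1, ]
  back <- matrix(0L, n, 4)
  for (t in seq_len(n)[-1]) {
    cand <- delta + log_trans # 4x4: prev x next
    back[t, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(back[t, ], 1:4)] + log_emit[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) {
    for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  path
}

#' Offline hypnogram smoothing
#'
#' Maximum a posteriori stage path under the transition model with per-epoch
#' emission scores given by the classifier stage distributions (uniform for
#' unscored epochs), decoded by dynamic programming (Viterbi); a rule pass
#' then replaces single-epoch stage islands (X, Y, X with Y != X) with the
#' flanking stage. Every epoch receives a stage: no `UNSCORED` remains.
#'
#' @param dists n x 4 matrix of stage probabilities (columns in [STAGES]
#'   order); rows of `NA` mark unscored epochs.
#' @param transitions a [fit_transitions] model.
#' @return a [hypnogram] of length n.
#' @export
smooth_offline <- function(dists, transitions) {
  dists <- as.matrix(dists)
  if (ncol(dists) != 4) sl_error("distribution stream must have 4 columns", "invalid_distribution")
  n <- nrow(dists)
  if (n < 1) sl_error("need at least one epoch", "too_short")
  emit <- dists
  bad <- !stats::complete.cases(emit)
  emit[bad, ] <- 0.25
  log_emit <- log(pmax(emit, 1e-12))
  log_trans <- log(pmax(transitions$matrix, 1e-12))
  log_init <- log(pmax(transitions$initial, 1e-12))
  path <- viterbi_path(log_emit, log_trans, log_init)
  stages <- STAGES[path]
  # island rule: iterate to a fixed point (bounded)
  for (pass in 1:5) {
    changed <- FALSE
    if (n >= 3) {
      for (i in 2:(n - 1)) {
        if (stages[i - 1] == stages[i + 1] && stages[i] != stages[i - 1]) {
          stages[i] <- stages[i - 1]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  hypnogram(stages)
}

## ---------------------------------------------------------------------------
## Classifiers

feature_schema <- function(feature_names) paste(feature_names, collapse = "|")

train_model <- function(x, y, kind, init = NULL, seed = 1, maxit = NULL, decay = 0.01) {
  x <- as.matrix(x)
  y <- as.character(y)
  keep <- y %in% STAGES & stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  absent <- setdiff(STAGES, unique(y))
  if (length(absent)) {
    sl_error(
      paste0("training labels lack stage(s): ", paste(absent, collapse = ", ")),
      "missing_stage"
    )
  }
  if (!is.null(init)) {
    if (init$schema != feature_schema(colnames(x))) {
      sl_error("feature schema mismatch between init model and data", "schema_mismatch")
    }
    center <- init$center; scale <- init$scale
  } else {
    center <- colMeans(x)
    scale <- pmax(apply(x, 2, stats::sd), 1e-8)
  }
  xs <- scale(x, center = center, scale = scale)
  yf <- factor(y, levels = STAGES)
  w <- (1 / table(yf))[yf]
  w <- as.numeric(w) * length(w) / sum(w)
  df <- data.frame(xs, check.names = FALSE)
  df$.stage <- yf
  # nnet's layout: per output unit one bias weight plus the model-matrix
  # columns including multinom's own intercept -> (p + 2) weights per class.
  # multinom freezes (masks) the nnet biases and the whole first-class unit;
  # those must stay 0 so the softmax over coef() is the model's forward pass.
  p1 <- ncol(x) + 1L
  free <- c(rep(FALSE, p1 + 1L), rep(c(FALSE, rep(TRUE, p1)), 3L))
  wts <- if (!is.null(init)) {
    init$wts
  } else {
    w0 <- numeric(length(free))
    w0[free] <- with_seed(seed, stats::runif(sum(free), -0.5, 0.5))
    w0
  }
  if (is.null(maxit)) maxit <- if (is.null(init)) 300 else 40
  fit <- nnet::multinom(
    .stage ~ ., data = df, weights = w, Wts = wts,
    maxit = maxit, decay = decay, trace = FALSE
  )
  coefs <- stats::coef(fit) # 3 x (p+1), baseline = first level (W)
  structure(
    list(
      kind = kind, coefs = coefs, wts = fit$wts,
      center = center, scale = scale,
      feature_names = colnames(x), schema = feature_schema(colnames(x)),
      levels = STAGES, n_train = nrow(x), seed = seed,
      warm_started = !is.null(init)
    ),
    class = "staging_model"
  )
}

predict_dist <- function(model, x) {
  x <- as.matrix(x)
  if (!identical(colnames(x), model$feature_names) ||
      feature_schema(colnames(x)) != model$schema) {
    sl_error("feature schema does not match the model", "schema_mismatch")
  }
  xs <- scale(x, center = model$center, scale = model$scale)
  eta <- cbind(1, xs) %*% t(model$coefs) # n x 3 (LS, DS, REM vs W)
  eta <- cbind(0, eta)
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  colnames(p) <- STAGES
  p
}

#' Train the primary (ExG) stage classifier
#'
#' Multinomial logistic regression on the ExG epoch features, with
#' inverse-class-frequency observation weights and deterministic seeded
#' initialization. Passing `init` warm-starts the optimizer from a previously
#' trained model's weights (and reuses its feature standardization), the
#' mechanism behind pre-training on a large population before fine-tuning on
#' little data.
#'
#' @param features epochs x features matrix with columns `EXG_FEATURE_NAMES`.
#' @param labels per-epoch stage labels (a [hypnogram] or character vector);
#'   `UNSCORED` epochs are dropped. All four stages must be present.
#' @param init optional model to warm-start from.
#' @param seed RNG seed for the cold-start weight initialization.
#' @param maxit optimizer iteration cap (defaults: 300 cold, 40 warm).
#' @param decay L2 weight decay.
#' @return an object of class `"staging_model"`.
#' @export
train_primary <- function(features, labels, init = NULL, seed = 1,
                          maxit = NULL, decay = 0.01) {
  train_model(features, labels, "primary", init, seed, maxit, decay)
}

#' @rdname train_primary
#' @param context_features epochs x features matrix of vitals context
#'   features (see [secondary_features]).
#' @export
train_secondary <- function(context_features, labels, init = NULL, seed = 1,
                            maxit = NULL, decay = 0.01) {
  train_model(context_features, labels, "secondary", init, seed, maxit, decay)
}

#' Predict per-epoch stage distributions
#'
#' Returns one probability row per epoch; epochs whose usable ExG channel set
#' is empty (`usable_n == 0`) — or, for the secondary model, whose vitals
#' context is entirely invalid — are emitted as `NA` rows (unscored). The
#' prediction is causal: each row depends only on that epoch's features.
#'
#' @param model a trained `"staging_model"`.
#' @param features epochs x features matrix matching the model schema.
#' @param usable_n optional integer vector: number of usable channels (or
#'   valid context rows) per epoch.
#' @return n x 4 matrix of probabilities (columns [STAGES]), `NA` rows for
#'   unscored epochs.
#' @export
predict_primary <- function(model, features, usable_n = NULL) {
  stopifnot(inherits(model, "staging_model"))
  features <- as.matrix(features)
  p <- matrix(NA_real_, nrow(features), 4, dimnames = list(NULL, STAGES))
  ok <- stats::complete.cases(features)
  if (!is.null(usable_n)) ok <- ok & usable_n > 0
  if (any(ok)) p[ok, ] <- predict_dist(model, features[ok, , drop = FALSE])
  p
}

#' @rdname predict_primary
#' @export
predict_secondary <- predict_primary

#' Stage labels from a distribution stream
#'
#' @param dists n x 4 probability matrix with `NA` rows for unscored epochs.
#' @return a [hypnogram] with `UNSCORED` for `NA` rows.
#' @export
argmax_stages <- function(dists) {
  dists <- as.matrix(dists)
  out <- rep(UNSCORED, nrow(dists))
  ok <- stats::complete.cases(dists)
  if (any(ok)) out[ok] <- STAGES[max.col(dists[ok, , drop = FALSE], ties.method = "first")]
  hypnogram(out)
}

#' Fuse primary and secondary streams in real time
#'
#' Epochs scored by the primary (ExG) classifier take its label. When the ExG
#' stream has been continuously unscorable for longer than `gap_min` minutes,
#' the secondary (vitals) classifier substitutes; shorter outage epochs stay
#' `UNSCORED`. Causal: the decision at epoch t uses only epochs up to t.
#'
#' @param primary n x 4 distribution matrix (`NA` rows = ExG-unscorable).
#' @param secondary n x 4 distribution matrix from the vitals classifier.
#' @param gap_min outage duration (minutes) before the secondary takes over.
#' @return list with `stages` (a [hypnogram]), `source` (per-epoch
#'   `"primary"`, `"secondary"` or `"unscored"`), and `dists` (the fused
#'   distribution stream, `NA` rows where unscored).
#' @export
fuse_realtime <- function(primary, secondary, gap_min = 5) {
  primary <- as.matrix(primary); secondary <- as.matrix(secondary)
  if (nrow(primary) != nrow(secondary)) sl_error("misaligned streams", "length_mismatch")
  n <- nrow(primary)
  gap_ep <- as.integer(round(gap_min * 2))
  p_ok <- stats::complete.cases(primary)
  s_ok <- stats::complete.cases(secondary)
  src <- rep("unscored", n)
  fused <- matrix(NA_real_, n, 4, dimnames = list(NULL, STAGES))
  run <- 0L
  for (i in seq_len(n)) {
    if (p_ok[i]) {
      run <- 0L
      src[i] <- "primary"
      fused[i, ] <- primary[i, ]
    } else {
      run <- run + 1L
      if (run > gap_ep && s_ok[i]) {
        src[i] <- "secondary"
        fused[i, ] <- secondary[i, ]
      }
    }
  }
  list(stages = argmax_stages(fused), source = src, dists = fused)
}

#' Missing-segment robustness experiment
#'
#' For each trial and each outage duration, a random contiguous segment of
#' each session's primary stream is marked ExG-unscorable. Scenario
#' `with_sml` fills the segment with the secondary classifier's predictions
#' before offline smoothing; scenario `without_sml` leaves it unscored and
#' lets the smoother bridge the gap. Accuracy is measured against ground
#' truth over all epochs.
#'
#' @param sessions list of sessions, each a list with `primary` (n x 4),
#'   `secondary` (n x 4) and `truth` (a [hypnogram]).
#' @param durations_min outage durations (minutes); durations not shorter
#'   than a session are skipped with a warning.
#' @param trials random trials per duration.
#' @param transitions a [fit_transitions] model for the smoother.
#' @param seed RNG seed.
#' @return data frame with `duration_min`, `scenario`, `accuracy` (mean over
#'   trials and sessions).
#' @export
missing_segment_experiment <- function(sessions, durations_min = c(5, 30, 75, 120),
                                       trials = 50, transitions, seed = 1) {
  res <- list()
  with_seed(seed, {
    for (d in durations_min) {
      len <- as.integer(round(d * 2))
      acc <- matrix(NA_real_, trials, 2, dimnames = list(NULL, c("with_sml", "without_sml")))
      for (tr in seq_len(trials)) {
        a_acc <- b_acc <- c()
        for (s in sessions) {
          n <- nrow(s$primary)
          if (len >= n) next
          pa <- pb <- s$primary
          if (len > 0) {
            start <- sample.int(n - len, 1)
            seg <- start:(start + len - 1)
            pa[seg, ] <- s$secondary[seg, , drop = FALSE]
            pb[seg, ] <- NA_real_
          }
          truth <- unclass(s$truth)
          a_acc <- c(a_acc, mean(unclass(smooth_offline(pa, transitions)) == truth))
          b_acc <- c(b_acc, mean(unclass(smooth_offline(pb, transitions)) == truth))
        }
        if (!length(a_acc)) {
          warning(sprintf("duration %g min >= session length: skipped", d))
          break
        }
        acc[tr, ] <- c(mean(a_acc), mean(b_acc))
      }
      res[[length(res) + 1]] <- data.frame(
        duration_min = d,
        scenario = c("with_sml", "without_sml"),
        accuracy = colMeans(acc, na.rm = TRUE)
      )
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Serialize / restore a staging model
#'
#' Models are stored as plain JSON (coefficients, scaling, schema and
#' training metadata), so they can be exchanged without binary formats.
#'
#' @param model a `"staging_model"`.
#' @param path JSON file path.
#' @return `read_staging_model` returns the model; `write_staging_model`
#'   returns `path` invisibly.
#' @export
write_staging_model <- function(model, path) {
  stopifnot(inherits(model, "staging_model"))
  obj <- unclass(model)
  obj$coefs <- list(values = as.vector(model$coefs), dim = dim(model$coefs),
                    rownames = rownames(model$coefs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_staging_model
#' @export
read_staging_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- matrix(obj$coefs$values, nrow = obj$coefs$dim[1])
  rownames(coefs) <- obj$coefs$rownames
  colnames(coefs) <- c("(Intercept)", obj$feature_names)
  obj$coefs <- coefs
  obj$center <- stats::setNames(as.numeric(obj$center), obj$feature_names)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$feature_names)
  class(obj) <- "staging_model"
  obj
}
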