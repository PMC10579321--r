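#' Build a pool of simulated nights with extracted features
#'
#' Each night gets its own seed (`seed_base + 17 * i`), its own simulated
#' subject (amplitude/noise/baseline variability), and the full feature
#' pipeline: ExG features under dynamic re-referencing plus vitals context
#' features.
#'
#' @param n_nights number of nights.
#' @param config a [sim_config] template (its seed is overridden per night).
#' @param seed_base base seed.
#' @param with_artifacts inject contact-loss artifacts?
#' @return list of nights, each with `x` (ExG features), `usable_n`, `sx`
#'   (vitals features), `s_valid`, `truth` (a [hypnogram]), and `truth_vitals`.
#' @export
build_night_set <- function(n_nights, config = sim_config(duration_min = 90),
                            seed_base = 1, with_artifacts = FALSE) {
  lapply(seq_len(n_nights), function(i) {
    cfg <- config
    cfg$seed <- seed_base + 17L * i
    night <- simulate_night(cfg, with_artifacts = with_artifacts)
    fx <- night_features(night$recording)
    vs <- vitals_series(night$recording)
    sx <- secondary_features(vs)
    n <- min(nrow(fx$features), nrow(sx$features), length(night$hypnogram))
    list(
      x = fx$features[seq_len(n), , drop = FALSE],
      usable_n = fx$usable_n[seq_len(n)],
      sx = sx$features[seq_len(n), , drop = FALSE],
      s_valid = sx$valid_n[seq_len(n)],
      truth = night$hypnogram[seq_len(n)],
      truth_vitals = night$truth[seq_len(n), , drop = FALSE]
    )
  })
}

pool_nights <- function(nights, what = c("x", "truth")) {
  x <- do.call(rbind, lapply(nights, `[[`, what[1]))
  y <- unlist(lapply(nights, function(n) unclass(n[[what[2]]])))
  keep <- stats::complete.cases(x) & y != UNSCORED
  list(x = x[keep, , drop = FALSE], y = y[keep])
}

#' Train primary and secondary models on a set of nights
#'
#' @param nights output of [build_night_set].
#' @param seed RNG seed for model initialization.
#' @return list with `pml`, `sml` and `transitions`.
#' @export
train_on_nights <- function(nights, seed = 1) {
  p <- pool_nights(nights, c("x", "truth"))
  s <- pool_nights(nights, c("sx", "truth"))
  list(
    pml = train_primary(p$x, p$y, seed = seed),
    sml = train_secondary(s$x, s$y, seed = seed),
    transitions = fit_transitions(lapply(nights, `[[`, "truth"))
  )
}

#' Synthetic staging benchmark
#'
#' Trains the primary (ExG) and secondary (vitals) classifiers on
#' `n_train` simulated nights and evaluates on `n_test` held-out nights
#' against generator truth: primary accuracy and Cohen's kappa over
#' ExG-scorable epochs, secondary-only accuracy over its valid epochs, and
#' smoothed full-coverage accuracy. Also reports sleep-onset-latency
#' deviations between the smoothed estimate and truth.
#'
#' @param n_train,n_test training and held-out nights.
#' @param config a [sim_config] template.
#' @param seed seed controlling night simulation and model initialization.
#' @return list of summary metrics.
#' @export
staging_benchmark <- function(n_train = 40, n_test = 10,
                              config = sim_config(duration_min = 90), seed = 1) {
  nights <- build_night_set(n_train + n_test, config, seed_base = seed * 101L)
  train <- nights[seq_len(n_train)]
  test <- nights[n_train + seq_len(n_test)]
  models <- train_on_nights(train, seed = seed)
  acc_p <- acc_s <- acc_sm <- kap <- numeric(0)
  sol_dev <- numeric(0)
  for (nt in test) {
    pd <- predict_primary(models$pml, nt$x, nt$usable_n)
    sd_ <- predict_secondary(models$sml, nt$sx, nt$s_valid)
    ag_p <- agreement(argmax_stages(pd), nt$truth)
    ag_s <- agreement(argmax_stages(sd_), nt$truth)
    acc_p <- c(acc_p, ag_p$accuracy)
    kap <- c(kap, ag_p$kappa)
    acc_s <- c(acc_s, ag_s$accuracy)
    sm <- smooth_offline(pd, models$transitions)
    acc_sm <- c(acc_sm, agreement(sm, nt$truth)$accuracy)
    est_sol <- detect_sol(unclass(sm))
    ref_sol <- detect_sol(unclass(nt$truth))
    if (!is.null(est_sol) && !is.null(ref_sol)) {
      sol_dev <- c(sol_dev, est_sol$epoch - ref_sol$epoch)
    }
  }
  list(
    primary_accuracy = mean(acc_p), primary_kappa = mean(kap),
    secondary_accuracy = mean(acc_s), smoothed_accuracy = mean(acc_sm),
    sol_deviations = sol_dev,
    sol_within5 = if (length(sol_dev)) mean(abs(sol_dev) <= 5) else NA_real_,
    models = models, per_night_primary = acc_p
  )
}

#' Pre-training (warm-start) comparison at low data volume
#'
#' Pre-trains the primary model on a large night pool, then for each seed
#' draws `n_small` nights and compares fine-tuning from the pre-trained
#' weights against cold-start training on the same small set, evaluated on a
#' held-out test set.
#'
#' @param nights a night pool from [build_night_set]; the first `n_pre`
#'   nights pre-train, the last `n_test` nights evaluate, the remainder is
#'   the small-data sampling pool.
#' @param n_pre,n_small,n_test pool sizes.
#' @param n_seeds paired repetitions.
#' @param seed base seed.
#' @return data frame with per-seed `warm` and `cold` held-out accuracies.
#' @export
pretraining_experiment <- function(nights, n_pre = 30, n_small = 2, n_test = 10,
                                   n_seeds = 5, seed = 1) {
  stopifnot(length(nights) >= n_pre + n_small + n_test)
  pre <- nights[seq_len(n_pre)]
  test <- nights[(length(nights) - n_test + 1):length(nights)]
  pool <- nights[(n_pre + 1):(length(nights) - n_test)]
  p_pre <- pool_nights(pre, c("x", "truth"))
  base <- train_primary(p_pre$x, p_pre$y, seed = seed)
  p_test <- pool_nights(test, c("x", "truth"))
  eval_acc <- function(model) {
    pred <- argmax_stages(predict_dist(model, p_test$x))
    mean(unclass(pred) == p_test$y)
  }
  res <- lapply(seq_len(n_seeds), function(s) {
    idx <- with_seed(seed + 1000L + s, sample(length(pool), n_small))
    p_small <- pool_nights(pool[idx], c("x", "truth"))
    # a 2-night draw can lack a stage; redraw deterministically if so
    tries <- 0
    while (length(setdiff(STAGES, unique(p_small$y))) && tries < 20) {
      tries <- tries + 1
      idx <- with_seed(seed + 1000L + s + 100L * tries, sample(length(pool), n_small))
      p_small <- pool_nights(pool[idx], c("x", "truth"))
    }
    warm <- train_primary(p_small$x, p_small$y, init = base, seed = seed + s)
    cold <- train_primary(p_small$x, p_small$y, seed = seed + s)
    data.frame(seed = s, warm = eval_acc(warm), cold = eval_acc(cold))
  })
  do.call(rbind, res)
}

#' Channel-selection recovery benchmark
#'
#' Simulates a night with injected contact-loss artifacts and scores the
#' epoch-by-channel detection of the quality module against the injected
#' mask (sensitivity/specificity), and compares the number of epochs left
#' with at least one derived channel under the dynamic versus the
#' contralateral-BE re-referencing scheme.
#'
#' @param config a [sim_config] template.
#' @param seed seed.
#' @return list with `sensitivity`, `specificity`, `scorable_dynamic`,
#'   `scorable_contralateral`, `fail_ratio`, `grid`, `mask`.
#' @export
quality_benchmark <- function(config = sim_config(duration_min = 120,
                                                  artifact_rate_per_h = 4),
                              seed = 1) {
  cfg <- config
  cfg$seed <- seed * 313L
  night <- simulate_night(cfg, with_artifacts = TRUE)
  grid <- assess_recording(night$recording)
  detected <- matrix(FALSE, nrow(night$mask), 6, dimnames = list(NULL, EXG_CHANNELS))
  for (ch in EXG_CHANNELS) {
    g <- grid[grid$channel == ch, ]
    detected[g$epoch + 1L, ch] <- !g$scorable
  }
  truth <- night$mask
  sens <- if (any(truth)) mean(detected[truth]) else NA_real_
  spec <- if (any(!truth)) mean(!detected[!truth]) else NA_real_
  n_ep <- nrow(truth)
  ns <- as.integer(night$recording$exg_rate * 30)
  dyn <- contra <- logical(n_ep)
  for (i in seq_len(n_ep)) {
    g <- grid[grid$epoch == i - 1L, ]
    usable <- g$channel[g$scorable]
    idx <- ((i - 1) * ns + 1):(i * ns)
    dyn[i] <- ncol(rereference(night$recording$exg[idx, , drop = FALSE], usable, "dynamic")) > 0
    contra[i] <- ncol(rereference(night$recording$exg[idx, , drop = FALSE], usable, "contralateral_be")) > 0
  }
  list(
    sensitivity = sens, specificity = spec,
    scorable_dynamic = sum(dyn), scorable_contralateral = sum(contra),
    fail_ratio = summarize_quality(grid, night$events)$fail_ratio,
    grid = grid, mask = truth
  )
}

#' Vitals recovery benchmark
#'
#' One default synthetic night: heart-rate and respiratory-rate mean
#' absolute error against generator truth over valid epochs, and posture
#' accuracy outside movement-burst epochs.
#'
#' @param config a [sim_config] template (default: 8-h night).
#' @param seed seed.
#' @return list with `hr_mae`, `hr_mape_pct`, `rr_mae`, `posture_accuracy`,
#'   `n_epochs`.
#' @export
vitals_benchmark <- function(config = sim_config(duration_min = 480), seed = 1) {
  cfg <- config
  cfg$seed <- seed * 77L
  hyp <- simulate_hypnogram(cfg)
  vit <- synthesize_vitals(hyp, cfg)
  rec <- recording(
    exg = matrix(0, length(vit$ppg) / vit$ppg_rate * 200, 6,
                 dimnames = list(NULL, EXG_CHANNELS)),
    exg_rate = 200, ppg = vit$ppg, ppg_rate = vit$ppg_rate,
    acc = vit$acc, acc_rate = vit$acc_rate
  )
  vs <- vitals_series(rec)
  n <- min(nrow(vs), nrow(vit$truth))
  vs <- vs[seq_len(n), ]; truth <- vit$truth[seq_len(n), ]
  hr <- mae_mape(ifelse(vs$hr_valid, vs$hr_bpm, NA), truth$hr_bpm)
  rr <- mae_mape(ifelse(vs$rr_valid, vs$rr_brpm, NA), truth$rr_brpm)
  still <- !truth$movement
  list(
    hr_mae = hr$mae, hr_mape_pct = hr$mape_pct, rr_mae = rr$mae,
    posture_accuracy = mean(vs$posture[still] == truth$posture[still], na.rm = TRUE),
    hr_valid_frac = mean(vs$hr_valid), rr_valid_frac = mean(vs$rr_valid),
    n_epochs = n
  )
}

#' Bandit convergence benchmark
#'
#' Sequential Thompson-sampling plays against arms with fixed true mean
#' rewards and Gaussian reward noise; reports the frequency of best-arm
#' selection over the final window.
#'
#' @param true_rewards named numeric of true mean rewards (PoAs slope units).
#' @param n_plays sequential plays.
#' @param reward_sd reward noise SD.
#' @param final_window plays counted for the best-arm rate.
#' @param seed seed.
#' @return list with `best_arm_rate`, `choices`, `posterior`.
#' @export
bandit_benchmark <- function(true_rewards = c(calm = 0.06, rain = 0.02),
                             n_plays = 500, reward_sd = 0.02,
                             final_window = 100, seed = 1) {
  post <- preference_posterior(names(true_rewards), obs_sd = reward_sd)
  choices <- character(n_plays)
  with_seed(seed, {
    for (i in seq_len(n_plays)) {
      c_i <- acr_recommend(post)
      r <- stats::rnorm(1, true_rewards[[c_i]], reward_sd)
      post <- acr_update(post, c_i, r)
      choices[i] <- c_i
    }
  })
  best <- names(true_rewards)[which.max(true_rewards)]
  tail_idx <- (n_plays - final_window + 1):n_plays
  list(
    best_arm_rate = mean(choices[tail_idx] == best),
    choices = choices, posterior = post
  )
}
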