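#' Initialize a probability-of-being-asleep trace
#'
#' PoAs summarizes recent stage-probability output as an exponentially
#' weighted moving average of the instantaneous sleep probability
#' `1 - p_W`:
#' `poas_t = alpha * poas_{t-1} + (1 - alpha) * (1 - p_w)`, starting at 0.
#' Unscored epochs carry the previous value forward.
#'
#' @param alpha smoothing parameter in (0, 1).
#' @param slope_window_min window (minutes) used by [poas_slope].
#' @return an object of class `"poas_trace"`.
#' @export
poas_trace <- function(alpha = 0.8, slope_window_min = 5) {
  if (!(alpha > 0 && alpha < 1)) sl_error("alpha must be in (0,1)", "invalid_config")
  structure(
    list(values = numeric(0), alpha = alpha, slope_window_min = slope_window_min),
    class = "poas_trace"
  )
}

#' Advance a PoAs trace by one epoch
#'
#' @param trace a [poas_trace].
#' @param dist named stage-probability vector (or one row of a distribution
#'   matrix), or `NA`/`NULL` for an unscored epoch.
#' @return the updated trace.
#' @export
update_poas <- function(trace, dist) {
  stopifnot(inherits(trace, "poas_trace"))
  prev <- if (length(trace$values)) trace$values[length(trace$values)] else 0
  unscored <- is.null(dist) || anyNA(dist)
  val <- if (unscored) prev else {
    p_w <- if (!is.null(names(dist))) dist[["W"]] else dist[1]
    trace$alpha * prev + (1 - trace$alpha) * (1 - p_w)
  }
  trace$values <- c(trace$values, min(1, max(0, val)))
  trace
}

#' Trailing PoAs slope
#'
#' Least-squares slope of PoAs against time over the trailing window.
#'
#' @param trace a [poas_trace].
#' @param window_min window length in minutes (defaults to the trace's own).
#' @return slope in PoAs units per minute, or `NA` (flagged `undefined`) when
#'   the trace does not yet cover the window.
#' @export
poas_slope <- function(trace, window_min = NULL) {
  stopifnot(inherits(trace, "poas_trace"))
  if (is.null(window_min)) window_min <- trace$slope_window_min
  k <- as.integer(round(window_min * 2))
  n <- length(trace$values)
  if (n < k) return(structure(NA_real_, undefined = TRUE))
  y <- trace$values[(n - k + 1):n]
  t_min <- (seq_len(k) - 1) * 0.5
  unname(stats::coef(stats::lm(y ~ t_min))[2])
}

#' Detect sleep onset in a causal stage stream
#'
#' Sleep-onset latency is the index of the first epoch beginning a run of at
#' least `k` consecutive non-wake epochs (the persistence guard ignores
#' shorter blips; `k = 1` gives the literal first-non-W rule). Minutes are
#' `index * 0.5` with 0-based indexing.
#'
#' @param stages character vector of stage labels (causal stream).
#' @param k persistence guard (consecutive non-W epochs required).
#' @return list with `epoch` (0-based index), `minutes`, and `detected_at`
#'   (0-based index of the epoch completing the guard), or `NULL` when no
#'   qualifying run exists.
#' @export
detect_sol <- function(stages, k = 3) {
  stages <- as.character(stages)
  run <- 0L
  for (i in seq_along(stages)) {
    if (stages[i] != "W" && stages[i] != UNSCORED) {
      run <- run + 1L
      if (run >= k) {
        start <- i - run + 1L
        return(list(epoch = start - 1L, minutes = (start - 1L) * 0.5,
                    detected_at = i - 1L))
      }
    } else {
      run <- 0L
    }
  }
  NULL
}

#' Audio content timeline
#'
#' One stimulation audio asset: a guided breathing voice (GBV) active from
#' `t0` and faded out by `t1`, a relaxation therapy voice (RTV) on
#' `[t1, t2]`, and background music (BM) from `t0` onward, the sole component
#' after `t2`, slowly fading thereafter.
#'
#' @param content_id character id.
#' @param t0,t1,t2 timeline breakpoints in minutes (`t0 <= t1 <= t2`).
#' @param fade_min fade duration (minutes) at component boundaries.
#' @param bm_fade_min time constant of the final background-music fade.
#' @return an object of class `"audio_content"`.
#' @export
audio_content <- function(content_id, t0 = 0, t1 = 8, t2 = 16,
                          fade_min = 0.5, bm_fade_min = 20) {
  if (!(t0 <= t1 && t1 <= t2)) sl_error("need t0 <= t1 <= t2", "invalid_timeline")
  if (fade_min < 0) sl_error("fades must be non-negative", "invalid_timeline")
  structure(as.list(environment()), class = "audio_content")
}

#' Component gains of the audio timeline
#'
#' @param content an [audio_content].
#' @param now_min elapsed session time in minutes.
#' @param sol_detected has sleep onset been detected?
#' @param cap_min hard stimulation cap (minutes); all gains are 0 once
#'   `now_min >= cap_min` or after sleep onset.
#' @return named gain vector `c(GBV, RTV, BM)` in `[0, 1]`.
#' @export
schedule_audio <- function(content, now_min, sol_detected = FALSE, cap_min = 50) {
  stopifnot(inherits(content, "audio_content"))
  if (now_min < 0) sl_error("now_min must be >= 0", "invalid_time")
  gains <- c(GBV = 0, RTV = 0, BM = 0)
  if (sol_detected || now_min >= cap_min || now_min < content$t0) return(gains)
  f <- content$fade_min
  ramp <- function(x) min(1, max(0, x))
  # GBV: on from t0, fading out to reach 0 at t1
  if (now_min < content$t1) {
    gains["GBV"] <- if (f > 0) ramp((content$t1 - now_min) / f) else 1
  }
  # RTV: on [t1, t2] with fade-in/out
  if (now_min >= content$t1 && now_min <= content$t2 && content$t2 > content$t1) {
    gains["RTV"] <- if (f > 0) {
      min(ramp((now_min - content$t1) / f), ramp((content$t2 - now_min) / f), 1)
    } else 1
  }
  # BM: slow fade-in from t0, sole component after t2, slow exponential fade
  gains["BM"] <- if (f > 0) ramp((now_min - content$t0) / f) else 1
  if (now_min > content$t2) {
    gains["BM"] <- gains["BM"] * exp(-(now_min - content$t2) / content$bm_fade_min)
  }
  gains
}

#' Automatic content switching decision
#'
#' Switch the background content iff the PoAs slope is below `threshold`
#' within the first `window_max_min` minutes of the session and at least
#' `dwell_min` minutes have passed since the last switch (or session start).
#'
#' @param slope current PoAs slope (per minute); `NA` slope never switches.
#' @param elapsed_min elapsed session time (minutes).
#' @param min_since_switch minutes since the last content switch.
#' @param threshold slope threshold (per minute).
#' @param window_max_min ACS is only active in this initial window.
#' @param dwell_min minimum dwell between switches.
#' @return logical.
#' @export
acs_should_switch <- function(slope, elapsed_min, min_since_switch,
                              threshold = 0.01, window_max_min = 20, dwell_min = 5) {
  if (is.na(slope)) return(FALSE)
  elapsed_min <= window_max_min && slope < threshold && min_since_switch >= dwell_min
}

## ---------------------------------------------------------------------------
## Thompson-sampling content recommendation

#' Audio-content preference posteriors
#'
#' Per-content normal value distributions for the Thompson-sampling
#' recommender. Rewards are PoAs slopes (per minute) observed while the
#' content played; updates are conjugate normal with known observation
#' variance, so the posterior variance strictly decreases with every
#' observation.
#'
#' @param content_ids character vector of catalog ids.
#' @param prior_mean,prior_sd prior value distribution per content.
#' @param obs_sd known observation (reward) standard deviation.
#' @return an object of class `"preference_posterior"`: data frame with
#'   `content_id`, `mu`, `var`, `n_obs`, plus attribute `obs_var`.
#' @export
preference_posterior <- function(content_ids, prior_mean = 0, prior_sd = 0.1,
                                 obs_sd = 0.02) {
  if (prior_sd <= 0 || obs_sd <= 0) sl_error("sds must be positive", "invalid_config")
  structure(
    data.frame(
      content_id = content_ids, mu = prior_mean, var = prior_sd^2, n_obs = 0L,
      stringsAsFactors = FALSE
    ),
    obs_var = obs_sd^2, class = c("preference_posterior", "data.frame")
  )
}

#' Conjugate posterior update from one reward
#'
#' `var_new = 1 / (1/var + 1/obs_var)`;
#' `mu_new = var_new * (mu/var + r/obs_var)`.
#'
#' @param posterior a [preference_posterior].
#' @param content_id content that produced the reward.
#' @param reward observed PoAs slope (per minute).
#' @return the updated posterior.
#' @export
acr_update <- function(posterior, content_id, reward) {
  i <- match(content_id, posterior$content_id)
  if (is.na(i)) sl_error(paste0("unknown audio content: ", content_id), "unknown_content")
  ov <- attr(posterior, "obs_var")
  v_new <- 1 / (1 / posterior$var[i] + 1 / ov)
  posterior$mu[i] <- v_new * (posterior$mu[i] / posterior$var[i] + reward / ov)
  posterior$var[i] <- v_new
  posterior$n_obs[i] <- posterior$n_obs[i] + 1L
  posterior
}

#' Thompson-sampling content recommendation
#'
#' One value is sampled from each eligible content's normal posterior and the
#' argmax is returned. When `last_content` is supplied (the most recently
#' used content), it is excluded from the draw and is never returned; at the
#' start of a fresh selection sequence pass `NULL` to make every content
#' eligible.
#'
#' @param posterior a [preference_posterior] with >= 2 contents.
#' @param last_content content id to exclude, or `NULL`.
#' @param seed optional RNG seed for a reproducible draw; the current RNG
#'   stream is used when `NULL`.
#' @return the selected content id.
#' @export
acr_recommend <- function(posterior, last_content = NULL, seed = NULL) {
  elig <- posterior
  if (!is.null(last_content)) {
    if (nrow(posterior) < 2) {
      sl_error("cannot exclude the last content from a 1-content catalog", "catalog_too_small")
    }
    elig <- posterior[posterior$content_id != last_content, , drop = FALSE]
  }
  draw <- function() stats::rnorm(nrow(elig), elig$mu, sqrt(elig$var))
  s <- if (is.null(seed)) draw() else with_seed(seed, draw())
  elig$content_id[which.max(s)]
}

## ---------------------------------------------------------------------------
## Closed-loop session

#' Closed-loop controller configuration
#'
#' @param alpha PoAs smoothing parameter.
#' @param slope_window_min PoAs slope window (minutes).
#' @param sol_k sleep-onset persistence guard (epochs).
#' @param acs_threshold,acs_window_max_min,acs_dwell_min see
#'   [acs_should_switch].
#' @param audio_cap_min hard stimulation cap (minutes).
#' @param session_max_min maximum session length simulated (minutes).
#' @param use_acr,use_acs enable content recommendation / switching; when
#'   disabled the content is drawn uniformly at random from the catalog.
#' @return named list.
#' @export
controller_config <- function(alpha = 0.8, slope_window_min = 5, sol_k = 3,
                              acs_threshold = 0.01, acs_window_max_min = 20,
                              acs_dwell_min = 5, audio_cap_min = 50,
                              session_max_min = 90, use_acr = TRUE, use_acs = TRUE) {
  as.list(environment())
}

#' Run one closed-loop stimulation session on a virtual sleeper
#'
#' Per 30-s epoch: advance the sleeper, update the PoAs trace from the
#' emitted stage distribution, check for sleep onset (stopping the audio on
#' detection or at the stimulation cap), and apply automatic content
#' switching. At session end, the PoAs slope over each content's play
#' interval becomes that content's reward and the preference posteriors are
#' updated.
#'
#' @param config a [controller_config].
#' @param sleeper a [virtual_sleeper].
#' @param catalog named list of [audio_content]s (or character ids, which get
#'   default timelines).
#' @param posterior a [preference_posterior] over the catalog.
#' @param seed RNG seed for the session.
#' @param last_content most recently used content from the previous session,
#'   or `NULL`.
#' @return list with `log` (per-epoch data frame: `epoch`, `poas`, `content`,
#'   `gain_gbv`, `gain_rtv`, `gain_bm`, `stage`), `sol_min` (detected
#'   sleep-onset latency, `NA` if none), `stop_reason`, `switches`,
#'   `rewards`, and the updated `posterior`.
#' @export
run_session <- function(config, sleeper, catalog, posterior, seed = 1,
                        last_content = NULL) {
  if (!length(catalog)) sl_error("catalog must be non-empty", "catalog_too_small")
  if (is.character(catalog)) {
    catalog <- stats::setNames(lapply(catalog, audio_content), catalog)
  }
  ids <- names(catalog)
  with_seed(seed, {
    pick <- function(last) {
      if (config$use_acr) acr_recommend(posterior, last) else sample(ids, 1)
    }
    content <- pick(last_content)
    play_start <- 0 # minutes
    intervals <- list() # content -> c(start, end)
    trace <- poas_trace(config$alpha, config$slope_window_min)
    state <- list(propensity = 0)
    n_max <- as.integer(config$session_max_min * 2)
    stages <- character(0)
    sol <- NULL
    audio_on <- TRUE
    stop_reason <- "session_end"
    last_switch_min <- 0
    log <- vector("list", n_max)
    for (i in seq_len(n_max)) {
      now_min <- (i - 1) * 0.5
      step <- simulate_closed_loop_step(
        sleeper, if (audio_on) content else NULL, state
      )
      state <- step$state
      trace <- update_poas(trace, step$dist)
      stages <- c(stages, STAGES[which.max(step$dist)])
      if (is.null(sol)) {
        sol <- detect_sol(stages, k = config$sol_k)
        if (!is.null(sol) && audio_on) {
          audio_on <- FALSE
          stop_reason <- "sol_detected"
          intervals[[length(intervals) + 1]] <- list(content = content, start = play_start, end = now_min)
        }
      }
      if (audio_on && now_min >= config$audio_cap_min) {
        audio_on <- FALSE
        stop_reason <- "cap_50min"
        intervals[[length(intervals) + 1]] <- list(content = content, start = play_start, end = now_min)
      }
      gains <- schedule_audio(
        catalog[[content]], now_min,
        sol_detected = !audio_on && stop_reason == "sol_detected",
        cap_min = config$audio_cap_min
      )
      if (!audio_on) gains[] <- 0
      if (audio_on && config$use_acs) {
        slope <- poas_slope(trace)
        if (acs_should_switch(slope, now_min, now_min - last_switch_min,
                              config$acs_threshold, config$acs_window_max_min,
                              config$acs_dwell_min)) {
          intervals[[length(intervals) + 1]] <- list(content = content, start = play_start, end = now_min)
          content <- pick(content)
          play_start <- now_min
          last_switch_min <- now_min
        }
      }
      log[[i]] <- data.frame(
        epoch = i - 1L, poas = trace$values[i], content = if (audio_on) content else NA_character_,
        gain_gbv = gains[["GBV"]], gain_rtv = gains[["RTV"]], gain_bm = gains[["BM"]],
        stage = stages[i]
      )
      if (!is.null(sol) && i - 1L >= sol$detected_at + 4L) break
    }
    if (audio_on) {
      intervals[[length(intervals) + 1]] <-
        list(content = content, start = play_start, end = (length(stages) - 1) * 0.5)
    }
    # rewards: PoAs slope over each content's play interval
    rewards <- list()
    for (iv in intervals) {
      i0 <- as.integer(iv$start * 2) + 1L
      i1 <- min(length(trace$values), as.integer(iv$end * 2) + 1L)
      if (i1 - i0 + 1 >= 4) {
        y <- trace$values[i0:i1]
        t_min <- (seq_along(y) - 1) * 0.5
        slope <- unname(stats::coef(stats::lm(y ~ t_min))[2])
        rewards[[length(rewards) + 1]] <- list(content = iv$content, reward = slope)
      }
    }
    if (config$use_acr) {
      for (r in rewards) posterior <- acr_update(posterior, r$content, r$reward)
    }
    list(
      log = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
      sol_min = if (is.null(sol)) NA_real_ else sol$minutes,
      stop_reason = stop_reason,
      switches = max(0L, length(intervals) - 1L),
      rewards = rewards,
      posterior = posterior,
      last_content = content
    )
  })
}

#' Paired closed-loop efficacy comparison
#'
#' Runs `n_nights` sessions on the same virtual sleeper under two arms with
#' paired per-night seeds: adaptive content selection (ACR + ACS, posteriors
#' carried across nights) versus uniform-random content with no switching.
#'
#' @param sleeper a [virtual_sleeper].
#' @param catalog content catalog (character ids or [audio_content] list).
#' @param n_nights sessions per arm.
#' @param seed base seed; night i uses `seed + i`.
#' @param config a [controller_config] (the control arm gets `use_acr =
#'   use_acs = FALSE`).
#' @return list with `sol_adaptive`, `sol_random` (per-night minutes; censored
#'   at `session_max_min` when no onset), their means, and the final
#'   `posterior`.
#' @export
closed_loop_ab <- function(sleeper, catalog = names(sleeper$content_effect),
                           n_nights = 20, seed = 1, config = controller_config()) {
  post <- preference_posterior(if (is.character(catalog)) catalog else names(catalog))
  cfg_rand <- config
  cfg_rand$use_acr <- FALSE
  cfg_rand$use_acs <- FALSE
  sol_a <- sol_r <- numeric(n_nights)
  last <- NULL
  for (i in seq_len(n_nights)) {
    a <- run_session(config, sleeper, catalog, post, seed = seed + i, last_content = last)
    post <- a$posterior
    last <- a$last_content
    r <- run_session(cfg_rand, sleeper, catalog,
                     preference_posterior(if (is.character(catalog)) catalog else names(catalog)),
                     seed = seed + i)
    sol_a[i] <- if (is.na(a$sol_min)) config$session_max_min else a$sol_min
    sol_r[i] <- if (is.na(r$sol_min)) config$session_max_min else r$sol_min
  }
  list(
    sol_adaptive = sol_a, sol_random = sol_r,
    mean_adaptive = mean(sol_a), mean_random = mean(sol_r),
    posterior = post
  )
}
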