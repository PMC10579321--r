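test_that("assess_channel flags degenerate and corrupted windows", {
  fs <- 200
  # all-zero window: fully flat, unscorable
  q0 <- assess_channel(numeric(fs * 30), fs)
  expect_equal(q0$flatline_frac, 1)
  expect_false(q0$scorable)

  # clean synthetic light-sleep epoch at default amplitudes: scorable
  cfg <- sim_config(seed = 8, duration_min = 2)
  rec <- synthesize_exg(hypnogram(rep("LS", 4)), cfg)
  q_ls <- assess_channel(rec$exg[1:6000, "OTE_L"], fs)
  expect_true(q_ls$scorable)

  # injected saturation artifact: saturation_frac above threshold
  ev <- data.frame(channel = "FH_L", start_epoch = 0L, n_epochs = 1L, kind = "saturation")
  inj <- inject_artifacts(rec, cfg, events = ev)
  q_sat <- assess_channel(inj$recording$exg[1:6000, "FH_L"], fs)
  expect_false(q_sat$scorable)
  expect_gt(q_sat$saturation_frac, 0.05)

  expect_error(assess_channel(numeric(100), fs), class = "invalid_window")
})

test_that("whole-night assessment matches the per-window path on clean and corrupted epochs", {
  cfg <- sim_config(seed = 13, duration_min = 10, artifact_rate_per_h = 0)
  night <- simulate_night(cfg)
  ev <- data.frame(
    channel = c("FH_L", "OTE_R"), start_epoch = c(2L, 10L),
    n_epochs = c(3L, 4L), kind = c("motion", "flatline")
  )
  inj <- inject_artifacts(night$recording, cfg, events = ev)
  grid <- assess_recording(inj$recording)
  for (i in c(0L, 3L, 11L)) {
    for (ch in c("FH_L", "OTE_R", "BE_L")) {
      win <- inj$recording$exg[(i * 6000 + 1):((i + 1) * 6000), ch]
      expect_equal(
        grid$scorable[grid$epoch == i & grid$channel == ch],
        assess_channel(win, 200)$scorable
      )
    }
  }
  # corrupted cells detected, clean cells not
  expect_false(any(grid$scorable[grid$channel == "FH_L" & grid$epoch %in% 2:4]))
  expect_false(any(grid$scorable[grid$channel == "OTE_R" & grid$epoch %in% 10:13]))
  expect_true(all(grid$scorable[grid$channel == "BE_L"]))
})

test_that("select_channels returns exactly the scorable set", {
  row <- data.frame(channel = EXG_CHANNELS, scorable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_setequal(select_channels(row), EXG_CHANNELS)
  row$scorable <- EXG_CHANNELS == "OTE_L"
  expect_identical(select_channels(row), "OTE_L")
  row$scorable <- FALSE
  expect_length(select_channels(row), 0)
})

test_that("re-referencing schemes follow their rules", {
  exg <- matrix(rnorm(600 * 6), 600, 6, dimnames = list(NULL, EXG_CHANNELS))
  # all usable, contralateral: exactly the four cross-side derivations
  d <- rereference(exg, EXG_CHANNELS, "contralateral_be")
  expect_setequal(colnames(d), c("FH_L-BE_R", "OTE_L-BE_R", "FH_R-BE_L", "OTE_R-BE_L"))
  expect_equal(d[, "FH_L-BE_R"], exg[, "FH_L"] - exg[, "BE_R"])
  # derived channels are plain sample-wise subtraction
  expect_identical(d[, "OTE_R-BE_L"], exg[, "OTE_R"] - exg[, "BE_L"])
  expect_equal(d[, "OTE_R-BE_L"] + exg[, "BE_L"], exg[, "OTE_R"], tolerance = 1e-12)

  # BE_R unusable, contralateral scheme: left-side derivations absent
  usable <- setdiff(EXG_CHANNELS, "BE_R")
  d2 <- rereference(exg, usable, "contralateral_be")
  expect_setequal(colnames(d2), c("FH_R-BE_L", "OTE_R-BE_L"))

  # BE_R unusable, dynamic: left targets fall back to the ipsilateral BE_L,
  # right targets keep their (usable) contralateral BE_L
  d3 <- rereference(exg, usable, "dynamic")
  expect_setequal(
    colnames(d3),
    c("FH_L-BE_L", "OTE_L-BE_L", "FH_R-BE_L", "OTE_R-BE_L")
  )
  # both BEs unusable, dynamic: raw pass-through of the targets
  d4 <- rereference(exg, c("FH_L", "OTE_R"), "dynamic")
  expect_setequal(colnames(d4), c("FH_L", "OTE_R"))
  expect_identical(attr(d4, "refs")[["FH_L"]], "raw")

  # none scheme passes usable channels through
  d5 <- rereference(exg, c("FH_L", "BE_L"), "none")
  expect_setequal(colnames(d5), c("FH_L", "BE_L"))

  expect_error(rereference(exg, "FH_X", "dynamic"), class = "invalid_channel")
})

test_that("dynamic scheme never yields fewer scorable epochs than contralateral", {
  exg <- matrix(rnorm(600 * 6), 600, 6, dimnames = list(NULL, EXG_CHANNELS))
  set.seed(20)
  for (i in 1:50) {
    usable <- EXG_CHANNELS[runif(6) > 0.4]
    n_dyn <- ncol(rereference(exg, usable, "dynamic"))
    n_con <- ncol(rereference(exg, usable, "contralateral_be"))
    expect_gte(n_dyn, n_con)
  }
})

test_that("quality summaries count failures and recovery time", {
  cfg <- sim_config(seed = 14, duration_min = 50, artifact_rate_per_h = 0)
  night <- simulate_night(cfg)
  grid0 <- assess_recording(night$recording)
  s0 <- summarize_quality(grid0)
  expect_true(all(s0$fail_ratio == 0))

  ev <- data.frame(channel = "FH_L", start_epoch = 30L, n_epochs = 10L, kind = "flatline")
  inj <- inject_artifacts(night$recording, cfg, events = ev)
  grid <- assess_recording(inj$recording)
  s <- summarize_quality(grid, ev)
  expect_equal(unname(s$fail_ratio["FH_L"]), 0.10)
  expect_true(all(s$fail_ratio[names(s$fail_ratio) != "FH_L"] == 0))
  # clean signal resumes on the next epoch: stabilization within 30 s
  expect_lte(s$stabilization$stabilization_s, 30)
})
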