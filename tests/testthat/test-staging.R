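test_that("consensus labeling: majority, unanimity, and agreement tie-break", {
  h <- function(...) hypnogram(c(...))
  expect_identical(
    stages_of(consensus_hypnogram(list(h("W"), h("W"), h("LS")))), "W"
  )
  expect_identical(
    stages_of(consensus_hypnogram(list(h("LS"), h("LS"), h("LS")))), "LS"
  )
  expect_error(consensus_hypnogram(list(h("W"), h("W"))), class = "too_few_scorers")
  expect_error(
    consensus_hypnogram(list(h("W"), h("W"), h("W", "LS"))),
    class = "length_mismatch"
  )

  # constructed 10-epoch study: technicians A/B/C, B has maximal mean
  # pairwise agreement, so the 3-way-tie epoch takes B's label
  A <- h("W", "W", "LS", "LS", "DS", "LS", "REM", "REM", "W", "DS")
  B <- h("W", "W", "LS", "LS", "DS", "DS", "REM", "REM", "LS", "W")
  C <- h("W", "LS", "LS", "DS", "DS", "REM", "REM", "W", "DS", "W")
  cons <- consensus_hypnogram(list(A, B, C))
  expect_identical(stages_of(cons)[9], "LS") # B's label on the 3-way-tie epoch
  expect_identical(stages_of(cons), oracle_consensus(cbind(stages_of(A), stages_of(B), stages_of(C))))
})

test_that("consensus matches the brute-force oracle on randomized panels", {
  set.seed(31)
  for (trial in 1:30) {
    k <- sample(c(3, 5), 1)
    n <- sample(5:40, 1)
    m <- matrix(sample(STAGES, n * k, replace = TRUE), n, k)
    got <- consensus_hypnogram(hyp_cols(m))
    expect_identical(stages_of(got), oracle_consensus(m))
  }
})

test_that("transition fitting counts bigrams with additive smoothing", {
  h <- hypnogram(c("W", "W", "LS", "LS"))
  tm0 <- fit_transitions(h, eps = 0)
  expect_equal(tm0$matrix["W", "W"], 0.5)
  expect_equal(tm0$matrix["W", "LS"], 0.5)
  expect_equal(tm0$matrix["LS", "LS"], 1)
  expect_equal(tm0$matrix["W", "DS"], 0) # unseen stays zero with eps = 0
  tm <- fit_transitions(h, eps = 1e-4)
  expect_equal(unname(rowSums(tm$matrix)), rep(1, 4))
  expect_true(all(tm$matrix > 0))
})

test_that("Viterbi smoothing equals exhaustive path enumeration on short streams", {
  set.seed(32)
  trans <- fit_transitions(hypnogram(
    sample(STAGES, 60, replace = TRUE, prob = c(0.2, 0.4, 0.25, 0.15))
  ))
  for (trial in 1:25) {
    n <- sample(2:7, 1)
    emit <- matrix(runif(n * 4), n, 4)
    emit <- emit / rowSums(emit)
    colnames(emit) <- STAGES
    # decode without the island rule interfering: compare raw MAP paths
    got <- somnoloop:::viterbi_path(log(emit), log(trans$matrix), log(trans$initial))
    expect_identical(got, unname(brute_force_path(emit, trans$matrix, trans$initial)))
  }
})

test_that("offline smoothing fills gaps, removes islands, keeps confident calls", {
  trans <- fit_transitions(hypnogram(rep(c("W", "W", "LS", "LS", "LS", "DS", "DS"), 20)))
  one_hot <- function(stages) {
    m <- matrix(1e-6, length(stages), 4, dimnames = list(NULL, STAGES))
    m[cbind(seq_along(stages), match(stages, STAGES))] <- 1
    m / rowSums(m)
  }
  # one-hot emissions consistent with high self-transition: passthrough
  s <- c("W", "W", "W", "LS", "LS", "DS", "DS", "DS")
  expect_identical(stages_of(smooth_offline(one_hot(s), trans)), s)

  # single-epoch island with strong flanks is removed by the rule pass
  m <- one_hot(c("W", "W", "LS", "W", "W"))
  expect_identical(stages_of(smooth_offline(m, trans)), rep("W", 5))

  # unscored rows are bridged: full coverage, no UNSCORED remains
  m2 <- one_hot(c("LS", "LS", "LS", "LS", "DS", "DS"))
  m2[3:4, ] <- NA
  sm <- smooth_offline(m2, trans)
  expect_false(any(stages_of(sm) == UNSCORED))
  expect_length(sm, 6)

  # property: no equal-flank single-epoch island survives the rule pass
  set.seed(33)
  for (trial in 1:20) {
    emit <- matrix(runif(40), 10, 4)
    emit <- emit / rowSums(emit)
    expect_true(no_flanked_islands(stages_of(smooth_offline(emit, trans))))
  }
})

test_that("training demands all stages, is seeded, and matches multinom probabilities", {
  pool <- benchmark_pool()
  p <- somnoloop:::pool_nights(pool[1:3], c("x", "truth"))
  expect_error(
    train_primary(p$x[p$y != "REM", ], p$y[p$y != "REM"]),
    class = "missing_stage"
  )
  m1 <- train_primary(p$x, p$y, seed = 4)
  m2 <- train_primary(p$x, p$y, seed = 4)
  expect_identical(m1$coefs, m2$coefs)

  # the package's softmax prediction equals nnet's own on the same fit
  xs <- scale(p$x, center = m1$center, scale = m1$scale)
  df <- data.frame(xs, check.names = FALSE)
  df$.stage <- factor(p$y, levels = STAGES)
  w <- (1 / table(df$.stage))[df$.stage]
  w <- as.numeric(w) * length(w) / sum(w)
  fit <- nnet::multinom(.stage ~ ., df, weights = w, Wts = m1$wts, maxit = 0, trace = FALSE)
  expect_equal(
    unname(predict(fit, df, type = "probs")[1:50, ]),
    unname(somnoloop:::predict_dist(m1, p$x[1:50, ])),
    tolerance = 1e-6
  )

  # schema guard
  bad <- p$x[1:5, rev(colnames(p$x))]
  expect_error(predict_primary(m1, bad), class = "schema_mismatch")
})

test_that("prediction routes empty usable sets to UNSCORED and normalizes rows", {
  models <- benchmark_models()
  nt <- benchmark_pool()[[45]]
  usable <- nt$usable_n
  usable[5:10] <- 0L
  pd <- predict_primary(models$pml, nt$x, usable)
  expect_true(all(is.na(pd[5:10, ])))
  ok <- stats::complete.cases(pd)
  expect_equal(unname(rowSums(pd[ok, ])), rep(1, sum(ok)), tolerance = 1e-9)
  st <- argmax_stages(pd)
  expect_true(all(unclass(st)[5:10] == UNSCORED))
  # secondary: an all-invalid context window is unscored
  sd_ <- predict_secondary(models$sml, nt$sx, rep(0L, nrow(nt$sx)))
  expect_true(all(is.na(sd_)))
})

test_that("real-time fusion substitutes the secondary stream only beyond the gap", {
  n <- 120
  prim <- matrix(rep(c(0.9, 0.06, 0.02, 0.02), each = n), n, 4,
                 dimnames = list(NULL, STAGES))
  sec <- matrix(rep(c(0.1, 0.7, 0.1, 0.1), each = n), n, 4,
                dimnames = list(NULL, STAGES))
  # all primary-scorable: output is the primary argmax everywhere
  f0 <- fuse_realtime(prim, sec)
  expect_true(all(f0$source == "primary"))
  expect_true(all(unclass(f0$stages) == "W"))

  # full-night outage: all secondary
  prim_na <- prim; prim_na[] <- NA
  f1 <- fuse_realtime(prim_na, sec, gap_min = 0)
  expect_true(all(f1$source == "secondary"))
  expect_true(all(unclass(f1$stages) == "LS"))

  # 20-min mid-night outage with a 5-min gap: exactly the epochs beyond the
  # gap threshold are tagged secondary
  prim2 <- prim
  prim2[41:80, ] <- NA
  f2 <- fuse_realtime(prim2, sec, gap_min = 5)
  expect_identical(which(f2$source == "secondary"), 51:80)
  expect_identical(which(f2$source == "unscored"), 41:50)

  # causality: truncation leaves the prefix unchanged
  f_short <- fuse_realtime(prim2[1:60, ], sec[1:60, ], gap_min = 5)
  expect_identical(f_short$source, f2$source[1:60])
  expect_error(fuse_realtime(prim, sec[1:10, ]), class = "length_mismatch")
})

test_that("staging models survive a JSON round trip", {
  models <- benchmark_models()
  f <- withr::local_tempfile(fileext = ".json")
  write_staging_model(models$pml, f)
  m2 <- read_staging_model(f)
  nt <- benchmark_pool()[[48]]
  expect_equal(
    predict_primary(models$pml, nt$x, nt$usable_n),
    predict_primary(m2, nt$x, nt$usable_n),
    tolerance = 1e-12
  )
})
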