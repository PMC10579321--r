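#' Agreement between an estimated and a reference hypnogram
#'
#' Epochs left unscored (in either input) are excluded from accuracy and
#' kappa but reported through `percent_scorable` (share of estimated epochs
#' that are scored). Cohen's kappa uses the standard chance-corrected
#' formula on the 4x4 scored-epoch confusion matrix; per-stage precision,
#' recall and F1 treat the reference as truth.
#'
#' @param est,ref [hypnogram]s of equal length.
#' @return list with `confusion` (5x5 including the unscored row/column),
#'   `accuracy`, `kappa`, `per_stage` (precision/recall/F1 data frame),
#'   `percent_scorable`, `n_scored`.
#' @export
agreement <- function(est, ref) {
  est <- as.character(est); ref <- as.character(ref)
  if (length(est) != length(ref)) sl_error("hypnograms differ in length", "length_mismatch")
  lv <- c(STAGES, UNSCORED)
  confusion <- table(
    factor(est, levels = lv), factor(ref, levels = lv),
    dnn = c("est", "ref")
  )
  scored <- est != UNSCORED & ref != UNSCORED
  n_scored <- sum(scored)
  cm <- confusion[STAGES, STAGES]
  if (n_scored > 0) {
    po <- sum(diag(cm)) / n_scored
    pe <- sum(rowSums(cm) * colSums(cm)) / n_scored^2
    kappa <- if (abs(1 - pe) < 1e-12) 1 else (po - pe) / (1 - pe)
    accuracy <- po
  } else {
    accuracy <- kappa <- NA_real_
  }
  per_stage <- do.call(rbind, lapply(STAGES, function(s) {
    tp <- cm[s, s]
    prec <- if (sum(cm[s, ]) > 0) tp / sum(cm[s, ]) else NA_real_
    rec <- if (sum(cm[, s]) > 0) tp / sum(cm[, s]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    data.frame(stage = s, precision = prec, recall = rec, f1 = f1)
  }))
  list(
    confusion = confusion, accuracy = accuracy, kappa = kappa,
    per_stage = per_stage,
    percent_scorable = 100 * mean(est != UNSCORED),
    n_scored = n_scored
  )
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences `a - b`; mean difference, SD of differences (n-1 denominator)
#' and 95\% limits of agreement `mean +/- 1.96 SD`.
#'
#' @param a,b paired numeric vectors (>= 2 pairs).
#' @return list with `mean_diff`, `sd_diff`, `loa` (length-2), `pairs`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) sl_error("inputs must be paired", "length_mismatch")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) sl_error("need at least 2 pairs", "too_few_pairs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  list(
    mean_diff = m, sd_diff = s, loa = c(m - 1.96 * s, m + 1.96 * s),
    pairs = data.frame(mean = (a + b) / 2, diff = d)
  )
}

#' Mean absolute error and mean absolute percentage error
#'
#' Invalid (`NA`) epochs are excluded pairwise; zero-reference epochs are
#' excluded from MAPE with a warning count.
#'
#' @param est,ref numeric series of equal length.
#' @return list with `mae`, `mape_pct`, `n`, `n_zero_ref_excluded`.
#' @export
mae_mape <- function(est, ref) {
  if (length(est) != length(ref)) sl_error("series differ in length", "length_mismatch")
  ok <- stats::complete.cases(est, ref)
  if (!any(ok)) sl_error("no valid pairs", "empty_series")
  e <- est[ok]; r <- ref[ok]
  nz <- r != 0
  if (any(!nz)) warning(sprintf("%d zero-reference epochs excluded from MAPE", sum(!nz)))
  list(
    mae = mean(abs(e - r)),
    mape_pct = if (any(nz)) 100 * mean(abs(e[nz] - r[nz]) / abs(r[nz])) else NA_real_,
    n = sum(ok), n_zero_ref_excluded = sum(!nz)
  )
}

#' Sleep-onset-latency deviation
#'
#' Signed epoch difference `est - ref`; the batch version summarizes the
#' distribution and the fraction of sessions within `tol` epochs.
#'
#' @param est,ref SOL estimates in epochs (scalars, or vectors for the
#'   batch version; `NA` marks sessions without a detected onset).
#' @param tol tolerance in epochs for the within-band fraction.
#' @return `sol_deviation`: signed difference in epochs (attribute
#'   `minutes`). `sol_deviation_batch`: list with `deviations`,
#'   `fraction_within`, `n`, `n_excluded`.
#' @export
sol_deviation <- function(est, ref) {
  if (is.na(est) || is.na(ref)) sl_error("both SOL values must be defined", "undefined_sol")
  d <- est - ref
  structure(d, minutes = d * 0.5)
}

#' @rdname sol_deviation
#' @export
sol_deviation_batch <- function(est, ref, tol = 5) {
  ok <- stats::complete.cases(est, ref)
  d <- est[ok] - ref[ok]
  list(
    deviations = d,
    fraction_within = if (length(d)) mean(abs(d) <= tol) else NA_real_,
    n = length(d), n_excluded = sum(!ok)
  )
}

#' One-way ANOVA and Tukey post-hoc comparisons
#'
#' Classical one-way analysis of variance across groups (via [stats::aov]);
#' Tukey's honest significant differences provide pairwise adjusted
#' p-values.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return `anova_oneway`: list with `F`, `p`, `df`. `tukey_posthoc`: data
#'   frame with `comparison`, `diff`, `p_adj`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) sl_error("need at least 2 groups", "too_few_groups")
  if (any(vapply(groups, length, 0L) < 2)) sl_error("each group needs >= 2 values", "degenerate_group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(f)) { f <- 0; p <- 1 } # zero residual variance across identical groups
  list(F = f, p = p, df = tab[["Df"]], fit = fit)
}

#' @rdname anova_oneway
#' @export
tukey_posthoc <- function(groups) {
  fit <- anova_oneway(groups)$fit
  tk <- stats::TukeyHSD(fit)$group
  data.frame(
    comparison = rownames(tk), diff = tk[, "diff"], p_adj = tk[, "p adj"],
    row.names = NULL
  )
}
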