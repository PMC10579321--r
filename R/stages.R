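#' Sleep-stage vocabulary
#'
#' The four scored stages used throughout the package, in canonical order:
#' wake (`W`), light sleep (`LS`, AASM N1+N2 merged), deep sleep (`DS`, N3)
#' and `REM`. Epochs that cannot be scored carry the sentinel `UNSCORED`.
#'
#' @format `STAGES` is a length-4 character vector; `UNSCORED` a length-1
#'   character scalar.
#' @export
STAGES <- c("W", "LS", "DS", "REM")

#' @rdname STAGES
#' @export
UNSCORED <- "UNSCORED"

# on-disk single-token codes (hypnogram CSV)
STAGE_CODES <- c(W = "W", LS = "LS", DS = "DS", REM = "R", UNSCORED = "U")
STAGE_FROM_CODE <- stats::setNames(names(STAGE_CODES), STAGE_CODES)

#' Construct a hypnogram
#'
#' A hypnogram is a sequence of per-epoch sleep-stage labels on a fixed 30-s
#' epoch grid. Labels must come from the five-symbol alphabet
#' `c(STAGES, UNSCORED)`.
#'
#' @param stages character vector of stage labels, one per 30-s epoch.
#' @param epoch_len_s epoch length in seconds; fixed at 30.
#' @return a character vector of class `"hypnogram"` with attribute
#'   `epoch_len_s`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30) {
  stages <- as.character(stages)
  if (epoch_len_s != 30) {
    sl_error("epoch_len_s must be 30", "invalid_hypnogram")
  }
  if (length(stages) < 1) {
    sl_error("a hypnogram needs at least one epoch", "invalid_hypnogram")
  }
  bad <- setdiff(unique(stages), c(STAGES, UNSCORED))
  if (length(bad)) {
    sl_error(
      paste0("unknown stage label(s): ", paste(bad, collapse = ", ")),
      "invalid_hypnogram"
    )
  }
  structure(stages, epoch_len_s = 30, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c(STAGES, UNSCORED)))
  cat(sprintf(
    "<hypnogram> %d epochs (%.1f min)\n", length(x), length(x) / 2
  ))
  print(tab)
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i) hypnogram(unclass(x)[i])

is_hypnogram <- function(x) inherits(x, "hypnogram")
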